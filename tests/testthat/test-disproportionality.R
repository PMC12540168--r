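test_that("contingency tables count reports once per PT with correct margins", {
  asg <- data.table::data.table(primaryid = c("t1", "t2"), drug = "drugA")
  reac <- data.table::data.table(
    primaryid = c("t1", "t1", "t2", "c1", "c2"),
    pt = c("Ptx", "Ptx", "Ptx", "Ptx", "Pty"))  # t1 lists Ptx twice
  universe <- c("t1", "t2", paste0("c", 1:10))
  tab <- build_contingency_tables(asg, reac, universe)
  row <- tab[pt == "Ptx"]
  expect_equal(unlist(row[, .(a, b, c_, d)]), c(a = 2L, b = 0L, c_ = 1L, d = 9L))
  # PT absent from comparator
  reac2 <- rbind(reac, data.table::data.table(primaryid = "t1", pt = "Ptz"))
  tab2 <- build_contingency_tables(asg, reac2, universe)
  expect_equal(tab2[pt == "Ptz", c_], 0L)
  # conservation: sum of a over PTs = total distinct report-PT pairs in target
  expect_equal(sum(tab2$a), 3L)
})

test_that("pair counting unit uses report-PT pairs as margins", {
  asg <- data.table::data.table(primaryid = "t1", drug = "drugA")
  reac <- data.table::data.table(primaryid = c("t1", "t1", "c1", "c1", "c2"),
                                 pt = c("X", "Y", "X", "Y", "Y"))
  tab <- build_contingency_tables(asg, reac, c("t1", "c1", "c2"), unit = "pair")
  expect_equal(tab[pt == "X", a + b], 2L)   # two target pairs
  expect_equal(tab[pt == "X", c_ + d], 3L)  # three comparator pairs
})

test_that("ROR and its Wald CI match hand-evaluated closed forms", {
  flat <- ror_stats(5, 5, 5, 5)
  expect_equal(flat$ror, 1)
  expect_true(flat$ror_ci_low < 1 && flat$ror_ci_high > 1)

  r <- ror_stats(36, 1000, 40, 33616)
  expect_equal(r$ror, 30.2544, tolerance = 1e-5)
  expect_equal(r$ror_ci_low, 19.205, tolerance = 1e-3)
  expect_equal(r$ror_ci_high, 47.66, tolerance = 1e-3)
  # point estimate is the geometric mean of the bounds
  expect_equal(r$ror, sqrt(r$ror_ci_low * r$ror_ci_high), tolerance = 1e-10)

  dbl <- ror_stats(72, 2000, 80, 67232)
  expect_equal(dbl$ror, r$ror)
  expect_true(dbl$ror_ci_low > r$ror_ci_low && dbl$ror_ci_high < r$ror_ci_high)

  expect_true(is.na(ror_stats(0, 10, 5, 100)$ror))
})

test_that("PRR and Pearson chi-squared match closed forms and chisq.test", {
  flat <- mhra_stats(5, 5, 5, 5)
  expect_equal(flat$prr, 1)
  expect_equal(flat$chi2, 0)

  m <- mhra_stats(36, 1000, 40, 33616)
  expect_equal(m$prr, 29.2378, tolerance = 1e-5)
  expect_equal(m$chi2, 517.86, tolerance = 1e-4)

  # symmetry under swapping the two rows
  expect_equal(mhra_stats(36, 1000, 40, 33616)$chi2,
               mhra_stats(40, 33616, 36, 1000)$chi2)

  # oracle: generic independence test without correction, random tables
  set.seed(402)
  for (i in 1:25) {
    cells <- rpois(4, lambda = sample(c(5, 50, 500), 1)) + 1
    ours <- mhra_stats(cells[1], cells[2], cells[3], cells[4])$chi2
    ref <- suppressWarnings(stats::chisq.test(
      matrix(cells, 2, byrow = TRUE), correct = FALSE))$statistic
    expect_equal(ours, unname(ref), tolerance = 1e-12)
    yates <- mhra_stats(cells[1], cells[2], cells[3], cells[4],
                        correction = "yates")$chi2
    ref_y <- suppressWarnings(stats::chisq.test(
      matrix(cells, 2, byrow = TRUE), correct = TRUE))$statistic
    expect_equal(yates, unname(ref_y), tolerance = 1e-12)
  }
})

test_that("BCPNN IC is near zero under independence and monotone in a", {
  ind <- bcpnn_stats(10, 990, 990, 98010)
  expect_lt(abs(ind$ic), 0.2)
  expect_lt(ind$ic025, 0)

  # raise a with all margins fixed: IC must increase
  base <- c(a = 10, b = 190, c = 90, d = 710)
  ics <- sapply(0:5, function(delta) {
    bcpnn_stats(base["a"] + delta, base["b"] - delta,
                base["c"] - delta, base["d"] + delta)$ic
  })
  expect_true(all(diff(ics) > 0))
})

test_that("closed-form BCPNN agrees with its Monte-Carlo posterior", {
  draws <- bcpnn_mc(36, 1000, 40, 33616, n_draws = 5e4, seed = 9)
  cf <- bcpnn_stats(36, 1000, 40, 33616)
  expect_equal(cf$ic, mean(draws), tolerance = 0.02)
  expect_equal(cf$ic025, unname(quantile(draws, 0.025)), tolerance = 0.1)
  # the plug-in approximation stays close for moderate cells
  ap <- bcpnn_stats(36, 1000, 40, 33616, method = "approx")
  expect_equal(ap$ic, cf$ic, tolerance = 0.05)
})

test_that("signal criteria implement the three published rules", {
  tab <- data.table::data.table(
    drug = "d", pt = c("tiny_a", "flat", "strong"),
    a = c(2L, 5L, 36L), b = c(10L, 5L, 1000L),
    c_ = c(1L, 5L, 40L), d = c(5000L, 5L, 33616L))
  st <- signal_stats(tab)
  expect_false(any(unlist(st[pt == "tiny_a",
                             .(flag_ror, flag_mhra, flag_bcpnn, flag_all3)])))
  expect_false(any(unlist(st[pt == "flat",
                             .(flag_ror, flag_mhra, flag_bcpnn, flag_all3)])))
  expect_true(all(unlist(st[pt == "strong",
                            .(flag_ror, flag_mhra, flag_bcpnn, flag_all3)])))
  expect_equal(st$flag_all3, st$flag_ror & st$flag_mhra & st$flag_bcpnn)
})

test_that("zero cells suppress frequentist statistics unless Haldane is chosen", {
  tab <- data.table::data.table(drug = "d", pt = "only_target",
                                a = 4L, b = 6L, c_ = 0L, d = 100L)
  sup <- signal_stats(tab)
  expect_true(is.na(sup$ror) && is.na(sup$prr))
  expect_false(sup$flag_ror || sup$flag_mhra)
  expect_false(is.na(sup$ic025))  # priors regularize the Bayesian statistic
  hal <- signal_stats(tab, zero_cell = "haldane")
  expect_false(is.na(hal$ror))
  expect_equal(hal$ror, (4.5 * 100.5) / (6.5 * 0.5))
})

test_that("signal ranking filters to triple-flagged PTs with stable ties", {
  st <- data.table::data.table(
    drug = "d", pt = c("B", "A", "C", "D"),
    a = c(10L, 10L, 8L, 50L), ror = c(3, 5, 9, 2),
    flag_all3 = c(TRUE, TRUE, TRUE, FALSE))
  top <- rank_signals(st, by = "count", n = 10)
  expect_equal(top$pt, c("A", "B", "C"))  # tie on a=10 broken by ror desc
  top1 <- rank_signals(st, by = "ror", n = 1)
  expect_equal(top1$pt, "C")
  expect_equal(nrow(rank_signals(st[pt == "A"], n = 10)), 1L)
})

test_that("Venn regions are disjoint and sum to flagged-by-any", {
  st <- data.table::data.table(
    drug = "d", pt = letters[1:5],
    flag_ror = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    flag_mhra = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    flag_bcpnn = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  st[, flag_all3 := flag_ror & flag_mhra & flag_bcpnn]
  v <- venn_counts(st)
  get <- function(r) v[region == r, count]
  expect_equal(get("all3"), 2L)
  expect_equal(get("ror_only"), 1L)
  expect_equal(get("mhra_only"), 1L)
  regions <- c("ror_only", "mhra_only", "bcpnn_only", "ror_mhra",
               "ror_bcpnn", "mhra_bcpnn", "all3")
  expect_equal(sum(sapply(regions, get)), get("any_method"))
})

test_that("stratified reruns restrict both populations and are deterministic", {
  sim <- small_sim()
  dd <- deduplicate_cases(sim$tables$demo)
  tabs <- filter_cases(sim$tables, dd$kept_primaryids)
  sel <- select_target_cases(tabs, mg_drug_dictionary())
  sr <- stratified_signals(sel$assignments, tabs, stratum = "sex")
  expect_setequal(names(sr$strata), c("F", "M"))
  expect_gt(sr$n_missing, 0L)
  # per-stratum a-cells cannot exceed the unstratified count
  full <- signal_stats(build_contingency_tables(
    sel$assignments, tabs$reac,
    universe_ids = data.table::as.data.table(tabs$demo)$primaryid))
  merged <- merge(sr$strata$F[, .(drug, pt, aF = a)],
                  full[, .(drug, pt, a)], by = c("drug", "pt"))
  expect_true(all(merged$aF <= merged$a))
  sr2 <- stratified_signals(sel$assignments, tabs, stratum = "sex")
  expect_equal(sr$strata$F, sr2$strata$F)

  # stratum without target cases yields an empty table with a warning
  asg_f <- sel$assignments[
    primaryid %in% data.table::as.data.table(tabs$demo)[
      toupper(sex) == "F", primaryid]]
  expect_warning(sr3 <- stratified_signals(asg_f, tabs, stratum = "sex"),
                 "no target cases")
  expect_equal(nrow(sr3$strata$M), 0L)
})

test_that("tables recovered from printed statistics reproduce the withheld one", {
  # forward-compute a known table, then recover it from three of its stats
  truth <- c(a = 36, b = 1000, c = 40, d = 33616)
  r <- ror_stats(truth[1], truth[2], truth[3], truth[4])
  m <- mhra_stats(truth[1], truth[2], truth[3], truth[4])
  rec <- recover_contingency(36, ror = r$ror, prr = m$prr, chi2 = m$chi2)
  expect_equal(c(rec$b, rec$c, rec$d), unname(truth[2:4]))
  rec2 <- recover_contingency(36, ror = r$ror, prr = m$prr,
                              ci_low = r$ror_ci_low, ci_high = r$ror_ci_high)
  expect_equal(c(rec2$b, rec2$c, rec2$d), unname(truth[2:4]))
  expect_error(recover_contingency(36, ror = 2, prr = 2), "three")
})
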