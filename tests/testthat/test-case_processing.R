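test_that("deduplication keeps latest FDA_DT, then highest PRIMARYID", {
  one <- demo_rows(1, 10, "20240101")
  expect_equal(deduplicate_cases(one)$demo$primaryid, "1")

  two <- demo_rows(c(1, 2), c(10, 10), c("20240101", "20240301"))
  dd <- deduplicate_cases(two)
  expect_equal(dd$demo$primaryid, "2")
  expect_equal(dd$n_removed, 1L)

  tie <- demo_rows(c(17, 42), c(10, 10), c("20240301", "20240301"))
  expect_equal(deduplicate_cases(tie)$demo$primaryid, "42")
})

test_that("deduplication orders partial FDA_DT by zero-filled key", {
  # a year-precision date sorts older than any full date in that year
  d <- demo_rows(c(5, 6), c(10, 10), c("2024", "20240101"))
  expect_equal(deduplicate_cases(d)$demo$primaryid, "6")
})

test_that("deduplication is idempotent and order-invariant", {
  set.seed(11)
  d <- demo_rows(primaryid = 1:40,
                 caseid = sample(1:12, 40, replace = TRUE),
                 fda_dt = format(as.Date("2024-01-01") +
                                   sample(0:300, 40, TRUE), "%Y%m%d"))
  once <- deduplicate_cases(d)
  twice <- deduplicate_cases(once$demo)
  expect_equal(twice$demo, once$demo)
  expect_equal(twice$n_removed, 0L)
  for (i in 1:5) {
    perm <- d[sample(nrow(d))]
    expect_equal(deduplicate_cases(perm)$demo[order(caseid)],
                 once$demo[order(caseid)])
  }
})

make_selection_tables <- function() {
  list(
    demo = demo_rows(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5),
                     c("20240110", "20240110", "20240110", "20240110", "20150101")),
    drug = data.table::data.table(
      primaryid = c("1", "2", "3", "4", "4", "5"),
      caseid = c("1", "2", "3", "4", "4", "5"),
      drug_seq = c("1", "1", "1", "1", "2", "1"),
      role_cod = c("PS", "SS", "PS", "PS", "PS", "PS"),
      drugname = c("SOLIRIS", "SOLIRIS", "Soliris", "SOLIRIS", "VYVGART", "SOLIRIS"),
      prod_ai = c("ECULIZUMAB", "ECULIZUMAB", "", "ECULIZUMAB", "EFGARTIGIMOD",
                  "ECULIZUMAB")),
    indi = data.table::data.table(
      primaryid = c("1", "2", "3", "4", "4", "5"),
      caseid = c("1", "2", "3", "4", "4", "5"),
      indi_drug_seq = c("1", "1", "1", "1", "2", "1"),
      indi_pt = c("Myasthenia gravis", "Myasthenia gravis",
                  "Paroxysmal nocturnal haemoglobinuria",
                  "Myasthenia gravis", "Myasthenia gravis",
                  "Myasthenia gravis")))
}

test_that("target selection enforces PS role, indication, window, ambiguity", {
  tabs <- make_selection_tables()
  dict <- load_drug_dictionary(dict_path())
  sel <- select_target_cases(tabs, dict)
  # report 1: PS Soliris + MG -> assigned; report 2: SS only -> no
  # report 3: PS but PNH indication -> no; report 4: matches two targets -> ambiguous
  # report 5: before approval -> no
  expect_equal(sel$assignments[drug == "eculizumab", primaryid], "1")
  expect_equal(sel$n_ambiguous, 1L)
  assigned <- length(unique(sel$assignments$primaryid))
  expect_equal(assigned + sel$n_ambiguous, 2L)  # reports passing all filters
})

test_that("indication may be required linked to the PS drug or anywhere", {
  tabs <- make_selection_tables()
  # move report 1's MG indication to a different drug_seq
  tabs$indi[primaryid == "1", indi_drug_seq := "9"]
  dict <- load_drug_dictionary(dict_path())
  linked <- select_target_cases(tabs, dict, indication_mode = "linked")
  expect_false("1" %in% linked$assignments$primaryid)
  anywhere <- select_target_cases(tabs, dict, indication_mode = "anywhere")
  expect_true("1" %in% anywhere$assignments$primaryid)
})

test_that("selection partitions the deduplicated reports", {
  sim <- small_sim()
  dd <- deduplicate_cases(sim$tables$demo)
  tabs <- filter_cases(sim$tables, dd$kept_primaryids)
  sel <- select_target_cases(tabs, mg_drug_dictionary())
  n_assigned <- length(unique(sel$assignments$primaryid))
  expect_true(n_assigned + sel$n_ambiguous <= nrow(dd$demo))
  # flow report stages are monotone non-increasing up to assignment
  fl <- sel$flow
  expect_true(fl[stage == "ps_match", count] <= fl[stage == "deduplicated_reports", count])
  expect_true(fl[stage == "ps_and_indication", count] <= fl[stage == "ps_match", count])
  expect_true(fl[stage == "within_approval_window", count] <=
                fl[stage == "ps_and_indication", count])
})

test_that("onset_days handles same-day, ordinary, negative and partial dates", {
  expect_equal(onset_days("20240110", "20240110"), 1L)
  expect_equal(onset_days("20240101", "20240131"), 30L)
  expect_true(is.na(onset_days("20240201", "20240115")))
  expect_true(is.na(onset_days("202401", "20240131")))   # month precision
  expect_true(is.na(onset_days("", "20240131")))
  # vectorized, and always >= 1 when defined
  d <- onset_days(rep("20240101", 3), c("20240101", "20240401", "20231231"))
  expect_equal(d, c(1L, 91L, NA_integer_))
})

test_that("case onset uses earliest day-precision start of the matched PS drug", {
  asg <- data.table::data.table(primaryid = "1", drug = "eculizumab", drug_seq = "1")
  tabs <- list(
    demo = data.table::data.table(primaryid = "1", caseid = "1",
                                  fda_dt = "20240301", event_dt = "20240215"),
    ther = data.table::data.table(
      primaryid = c("1", "1", "1"), caseid = c("1", "1", "1"),
      drug_seq = c("1", "1", "2"),
      start_dt = c("20240210", "20240101", "20231201"), end_dt = ""))
  # two THER rows for the matched seq: earliest (20240101) anchors onset;
  # the seq-2 row belongs to another drug and is ignored
  out <- case_onset_days(asg, tabs)
  expect_equal(out$onset, as.integer(as.Date("2024-02-15") - as.Date("2024-01-01")))
})
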