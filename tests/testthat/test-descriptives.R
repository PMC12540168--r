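test_that("percentage cells reproduce printed-table arithmetic", {
  expect_equal(percentage(1980, 1980 + 3296), 37.53)
  expect_equal(percentage(55, 370), 14.86)
  expect_equal(percentage(0, 5), 0.00)
  expect_true(is.na(percentage(0, 0)))
  # half-up, not banker's: 0.125 of 1000 is 12.50, .005 rounds up
  expect_equal(percentage(1, 8), 12.5)
  expect_equal(round_half_up(2.675, 2), 2.68)
})

test_that("onset bins partition days at the documented boundaries", {
  expect_equal(as.character(bin_onset(c(1, 30, 31, 60, 61, 90, 91, NA))),
               c("D0_30", "D0_30", "D31_60", "D31_60", "D61_90", "D61_90",
                 "D90PLUS", "NOT_SPECIFIED"))
})

test_that("continuous summaries use sample SD and interpolated quartiles", {
  s1 <- continuous_summary(5)
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sd))
  expect_equal(s1$median, 5)

  s <- continuous_summary(c(1, 2, 3, 4))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, sqrt(5 / 3))
  expect_equal(s$median, 2.5)
  expect_equal(s$q1, 1.75)
  expect_equal(s$q3, 3.25)

  shuffled <- continuous_summary(c(3, 1, 4, 2))
  expect_equal(shuffled, s)

  empty <- continuous_summary(c(NA_real_, NA_real_))
  expect_equal(empty$n, 0L)
  expect_true(all(is.na(unlist(empty[, -1]))))
})

test_that("trend counts conserve totals across granularities", {
  expect_equal(trend_counts("20190415")$period, "2019Q2")
  tc <- trend_counts(c("20190415", "20191001", "20191115", "2020"))
  expect_equal(sum(tc$count), 4L)
  expect_equal(nrow(tc), 3L)  # 2019Q2, 2019Q4, year-only 2020
  ty <- trend_counts(c("20190415", "20191001", "20191115", "2020"), "year")
  expect_equal(setNames(ty$count, ty$period), c("2019" = 3L, "2020" = 1L))
})

test_that("SOC rollup conserves report mass and pools unmapped PTs", {
  m <- load_soc_map(soc_map_path(c("pt\tsoc",
                                   "Headache\tNervous system disorders",
                                   "Migraine\tNervous system disorders")))
  pos <- data.table::data.table(pt = c("Headache", "Migraine", "Vertigo"),
                                reports = c(10L, 5L, 2L))
  roll <- soc_rollup(pos, m)
  expect_equal(roll[soc == "Nervous system disorders", reports], 15L)
  expect_equal(roll[soc == "UNMAPPED_SOC", reports], 2L)
  expect_equal(sum(roll$reports), sum(pos$reports))
  expect_equal(nrow(soc_rollup(pos[0], m)), 0L)
})

test_that("PT onset profiles count only reports with defined onset", {
  reac <- data.table::data.table(
    primaryid = c("1", "1", "2", "3"), caseid = c("1", "1", "2", "3"),
    pt = c("Headache", "Nausea", "Headache", "Headache"))
  onset <- data.table::data.table(
    primaryid = c("1", "2", "3"), drug = "eculizumab",
    onset = c(12L, 95L, NA_integer_))
  sp <- data.table::data.table(drug = "eculizumab",
                               pt = c("Headache", "Vertigo"))
  prof <- pt_onset_profile(sp, reac, onset)
  expect_equal(prof[pt == "Headache" & bin == "D0_30", count], 1L)
  expect_equal(prof[pt == "Headache" & bin == "D90PLUS", count], 1L)
  expect_equal(prof[pt == "Headache", sum(count)], 2L)  # report 3 has no onset
  expect_equal(prof[pt == "Vertigo", sum(count)], 0L)
})

test_that("characteristics blocks sum to each drug's total", {
  sim <- small_sim()
  dd <- deduplicate_cases(sim$tables$demo)
  tabs <- filter_cases(sim$tables, dd$kept_primaryids)
  sel <- select_target_cases(tabs, mg_drug_dictionary())
  ch <- characteristics_table(sel$assignments, tabs)
  totals <- ch$categorical[, .(n = data.table::uniqueN(total)), by = drug]
  expect_true(all(totals$n == 1L))
  sums <- ch$categorical[!block %in% c("outcome", "country"),
                         .(s = sum(count), total = total[1]),
                         by = .(drug, block)]
  expect_true(all(sums$s == sums$total))
  pct <- ch$categorical[!block %in% c("outcome", "country"),
                        .(p = sum(percent)), by = .(drug, block)]
  expect_true(all(pct$p >= 99.9 & pct$p <= 100.1))
  # age conversion sanity: simulated mean age is around 60 years
  age <- ch$continuous[variable == "age_years"]
  expect_true(all(age$mean > 50 & age$mean < 70))
})

test_that("age and weight unit codes convert as documented", {
  sim <- small_sim()  # ensures package loaded; conversion is pure arithmetic
  demo <- data.table::data.table(
    primaryid = as.character(1:6), caseid = as.character(1:6),
    fda_dt = "20240101", event_dt = "",
    age = c("6", "60", "24", "730.5", "130", ""),
    age_cod = c("DEC", "YR", "MON", "DY", "YR", ""),
    sex = "F", wt = c("220.462", "80", "", "", "", ""),
    wt_cod = c("LBS", "KG", "", "", "", ""),
    occp_cod = "CN", reporter_country = "US")
  asg <- data.table::data.table(primaryid = as.character(1:6),
                                drug = "eculizumab", drug_seq = "1")
  tabs <- list(demo = demo, ther = demo[0, .(primaryid, caseid)],
               outc = demo[0, .(primaryid, caseid)])
  tabs$ther <- data.table::data.table(primaryid = character(0),
                                      caseid = character(0), drug_seq = character(0),
                                      start_dt = character(0), end_dt = character(0))
  tabs$outc <- data.table::data.table(primaryid = character(0),
                                      caseid = character(0), outc_cod = character(0))
  ch <- characteristics_table(asg, tabs)
  age <- ch$continuous[variable == "age_years"]
  # DEC=decades(x10), MON/12, DY/365.25; age 130 and blank are missing
  expect_equal(age$n, 4L)
  expect_equal(age$min, 2)
  expect_equal(age$max, 60)
  wt <- ch$continuous[variable == "weight_kg"]
  expect_equal(wt$n, 2L)
  expect_equal(wt$max, 100, tolerance = 1e-3)  # 220.462 lbs -> ~100 kg
})
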