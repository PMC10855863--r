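# Cohort I/O, validation, MoM attachment, filtering, windows, summary.

test_that("read_cohort loads well-formed files and normalizes group case", {
  tbl <- make_cohort_tbl()
  tbl$group <- c("rpl", "Control", "CONTROL")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, path, na = "")
  cohort <- read_cohort(path)
  expect_identical(nrow(cohort), 3L)
  expect_identical(as.character(cohort$group), c("RPL", "CONTROL", "CONTROL"))
})

test_that("read_cohort reports schema and row-level problems", {
  tbl <- make_cohort_tbl()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(tbl, -"ga_days"), path, na = "")
  expect_error(read_cohort(path), "ga_days")

  bad <- make_cohort_tbl()
  bad$group[2] <- "patient"
  expect_error(validate_cohort(bad), "rows 2")
  bad2 <- make_cohort_tbl()
  bad2$ga_days[3] <- 120L
  expect_error(validate_cohort(bad2), "rows 3")
  bad3 <- make_cohort_tbl()
  bad3$conc_pappa[1] <- -2
  expect_error(validate_cohort(bad3), "conc_pappa")
})

test_that("validation flags below-detection-limit values without dropping them", {
  tbl <- make_cohort_tbl()
  tbl$conc_plgf[1] <- 2.0 # limit is 3.6 pg/mL
  cohort <- validate_cohort(tbl)
  expect_identical(nrow(cohort), 3L)
  expect_true(cohort$below_limit_plgf[1])
  expect_false(any(cohort$below_limit_plgf[-1]))
})

test_that("attach_moms respects per-analyte windows and never drops subjects", {
  tbl <- make_cohort_tbl(ga = c(45L, 50L, 63L))
  tbl$conc_free_bhcg[3] <- daily_median("free_bhcg", 63)
  tbl$conc_pappa[3] <- daily_median("pappa", 63)
  tbl$conc_plgf[3] <- daily_median("plgf", 63)
  moms <- attach_moms(tbl)
  expect_identical(dplyr::n_distinct(moms$subject_id), 3L)
  expect_identical(nrow(moms), 9L)
  at <- function(id, a) dplyr::filter(moms, subject_id == id, analyte == a)
  # day 45 precedes every reference window
  expect_false(any(dplyr::filter(moms, subject_id == "P01")$in_reference_range))
  expect_true(all(is.na(dplyr::filter(moms, subject_id == "P01")$dmom)))
  # day 50: free beta-hCG and PAPP-A valid, PlGF (from 56) not
  expect_true(at("P02", "free_bhcg")$in_reference_range)
  expect_true(at("P02", "pappa")$in_reference_range)
  expect_false(at("P02", "plgf")$in_reference_range)
  # concentrations set to the daily medians give dMoM 1 for all three
  expect_equal(dplyr::filter(moms, subject_id == "P03")$dmom, rep(1, 3),
               tolerance = 1e-12)
})

test_that("filter_for_analysis keeps complete cases per panel and counts groups", {
  tbl <- make_cohort_tbl(ga = c(98L, 60L, 70L), group = c("RPL", "RPL", "CONTROL"))
  moms <- attach_moms(tbl)
  # day 98 is outside 49-97: dropped for a free beta-hCG panel...
  kept <- filter_for_analysis(moms, "free_bhcg")
  expect_false("P01" %in% kept$subject_id)
  # ...but retained for PlGF, whose window runs to day 98
  kept_plgf <- filter_for_analysis(moms, "plgf")
  expect_true("P01" %in% kept_plgf$subject_id)
  counts <- attr(kept_plgf, "group_counts")
  expect_identical(counts$n[counts$group == "RPL"], 2L) # days 98 and 60
  # idempotence
  again <- filter_for_analysis(kept, "free_bhcg")
  expect_equal(again, kept, ignore_attr = TRUE)
  expect_equal(attr(again, "group_counts")$n, attr(kept, "group_counts")$n)
  # retained counts are monotone non-increasing as the panel grows
  n_kept <- function(a) dplyr::n_distinct(filter_for_analysis(moms, a)$subject_id)
  expect_gte(n_kept("pappa"), n_kept(c("pappa", "plgf")))
  expect_gte(n_kept(c("pappa", "plgf")), n_kept(analytes()))
  # an impossible panel is an explicit error
  early_only <- attach_moms(make_cohort_tbl(ga = c(50L, 51L, 52L)))
  expect_error(filter_for_analysis(early_only, "plgf"), "No subject")
})

test_that("strict mode drops below-limit subjects from a panel", {
  tbl <- make_cohort_tbl(ga = c(60L, 60L, 60L))
  tbl$conc_plgf[2] <- 2.0
  moms <- attach_moms(tbl)
  default <- filter_for_analysis(moms, "plgf")
  strict <- filter_for_analysis(moms, "plgf", exclude_below_limit = TRUE)
  expect_true("P02" %in% default$subject_id)
  expect_false("P02" %in% strict$subject_id)
})

test_that("split_windows partitions at 63 days (9 completed weeks)", {
  moms <- attach_moms(make_cohort_tbl(ga = c(62L, 63L, 80L)))
  parts <- split_windows(moms)
  expect_identical(unique(parts$early$subject_id), "P01")
  expect_setequal(unique(parts$late$subject_id), c("P02", "P03"))
  expect_identical(nrow(parts$early) + nrow(parts$late), nrow(moms))
  expect_length(intersect(parts$early$subject_id, parts$late$subject_id), 0)
  empty <- split_windows(moms[0, ])
  expect_identical(nrow(empty$early), 0L)
  expect_identical(nrow(empty$late), 0L)
  expect_identical(as.character(ga_window(c(62, 63))), c("early", "late"))
})

test_that("summarize_cohort reports the documented statistics", {
  tbl <- make_cohort_tbl(ga = c(49L, 63L, 70L, 84L),
                         group = c("RPL", "CONTROL", "CONTROL", "CONTROL"))
  tbl$maternal_age_years <- c(35, 30, 40, 30)
  tbl$gravidity <- c(2, 1, 2, 3)
  s <- summarize_cohort(tbl)
  ctl <- s[s$group == "CONTROL", ]
  expect_equal(ctl$maternal_age_mean, mean(c(30, 40, 30)))
  expect_equal(ctl$ga_weeks_mean, mean(c(63, 70, 84) / 7))
  # single-subject group: SD undefined, reported as NA
  expect_true(is.na(s$maternal_age_sd[s$group == "RPL"]))
  # type-7 interpolation quantiles
  tbl2 <- make_cohort_tbl(ga = c(60L, 60L, 60L, 60L),
                          group = rep("CONTROL", 4))
  tbl2$gravidity <- 1:4
  s2 <- summarize_cohort(tbl2)
  expect_equal(s2$gravidity_median, 2.5)
  expect_equal(s2$gravidity_q1, 1.75)
  expect_equal(s2$gravidity_q3, 3.25)
})
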