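# Synthetic cohort generator: calibration, determinism, parameter
# recovery, floors, matching.

test_that("binormal sigma calibration matches the hand-computed inversion", {
  # log2(1.66/0.39) = 2.0897, qnorm(0.880) = 1.17499
  expect_equal(calibrate_sigma_from_auc(1.66, 0.39, 0.880), 1.2575,
               tolerance = 1e-4)
  expect_equal(calibrate_sigma_from_auc(1.52, 1.01, 0.644), 1.1295,
               tolerance = 1e-4)
  expect_equal(calibrate_sigma_from_auc(1.2, 0.05, 0.975), 1.6541,
               tolerance = 1e-4)
  # symmetric in the direction of the effect
  expect_equal(calibrate_sigma_from_auc(0.39, 1.66, 0.88),
               calibrate_sigma_from_auc(1.66, 0.39, 0.88))
  # perfect-separation limit: sigma -> 0
  expect_lt(calibrate_sigma_from_auc(2, 1, 0.9999999),
            calibrate_sigma_from_auc(2, 1, 0.99))
  expect_lt(calibrate_sigma_from_auc(2, 1, 0.9999999), 0.2)
  expect_error(calibrate_sigma_from_auc(1, 1, 0.9), "Equal")
  expect_error(calibrate_sigma_from_auc(2, 1, 0.5), "between")
  expect_error(calibrate_sigma_from_auc(2, 1, 1), "between")
})

test_that("generation is deterministic and respects sizes, ranges and floors", {
  cfg <- generator_config(seed = 9, matching_enabled = FALSE)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, p1, config = cfg)
  write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(file.exists(paste0(p1, ".yaml")))

  expect_identical(sum(c1$group == "RPL"), 14L)
  expect_identical(sum(c1$group == "CONTROL"), 30L)
  rng_r <- range(c1$ga_days[c1$group == "RPL"])
  rng_c <- range(c1$ga_days[c1$group == "CONTROL"])
  expect_true(rng_r[1] >= 42 && rng_r[2] <= 91)
  expect_true(rng_c[1] >= 35 && rng_c[2] <= 83)
  lims <- detection_limits()
  for (a in analytes()) {
    expect_true(all(c1[[paste0("conc_", a)]] >= lims[[a]]))
  }
  # control-only cohort
  only_ctl <- generate_cohort(generator_config(n_rpl = 0, seed = 3))
  expect_identical(nrow(only_ctl), 30L)
  expect_true(all(only_ctl$group == "CONTROL"))
})

test_that("large cohorts recover the configured locations and scales", {
  cfg <- generator_config(n_rpl = 5000, n_control = 5000,
                          matching_enabled = FALSE, seed = 21)
  moms <- attach_moms(generate_cohort(cfg))
  cells <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(moms, .data$in_reference_range),
                    .data$analyte, .data$group, .data$window),
    m = mean(.data$log2_dmom), s = stats::sd(.data$log2_dmom),
    n = dplyr::n(), .groups = "drop")
  lims <- detection_limits()
  # expected mean of the floor-censored log2 dMoM, averaged over the
  # cell's uniformly sampled gestational days: the detection floor at
  # concentration L on day g censors log2 dMoM at t(g) = log2(L/median(g))
  censored_mean <- function(mu, sigma, t) {
    a <- (t - mu) / sigma
    t * stats::pnorm(a) + mu * (1 - stats::pnorm(a)) + sigma * stats::dnorm(a)
  }
  expect_identical(nrow(cells), 12L) # 3 analytes x 2 groups x 2 windows
  for (i in seq_len(nrow(cells))) {
    a <- cells$analyte[i]; g <- as.character(cells$group[i])
    w <- as.character(cells$window[i])
    loc <- cfg$dmom_location[[a]][[g]][[w]]
    sig <- cfg$sigma_log2[[a]]
    rng <- if (g == "RPL") cfg$ga_range_rpl else cfg$ga_range_control
    dom <- ga_domain(a)
    days <- max(rng[1], dom[1]):min(rng[2], dom[2])
    days <- days[if (w == "early") days < 63 else days >= 63]
    thresh <- log2(lims[[a]] / daily_median(a, days))
    expected_m <- mean(censored_mean(log2(loc), sig, thresh))
    censor_mass <- mean(stats::pnorm((thresh - log2(loc)) / sig))
    se <- sig / sqrt(cells$n[i]) # upper bound: censoring shrinks the SD
    expect_lt(abs(cells$m[i] - expected_m), 3 * se)
    if (censor_mass < 0.02) {
      expect_lt(abs(cells$s[i] - sig) / sig, 0.05)
    }
  }
})

test_that("cohorts calibrated to a target AUC attain it empirically", {
  for (target in c(0.70, 0.88)) {
    sig <- calibrate_sigma_from_auc(1.6, 0.4, target)
    f <- binormal_feature(2000, 0.4, 1.6, sig, seed = round(100 * target))
    auc <- roc_auc(empirical_roc(-f$x[, 1], f$y))
    expect_lt(abs(auc - target), 3 * auc_se(target, 2000, 2000))
  }
})

test_that("matching guarantees two controls within a week, or fails loudly", {
  cfg <- generator_config(n_rpl = 10, n_control = 25,
                          ga_range_rpl = c(49L, 83L), seed = 5)
  cohort <- generate_cohort(cfg)
  ga_ctl <- cohort$ga_days[cohort$group == "CONTROL"]
  for (g in cohort$ga_days[cohort$group == "RPL"]) {
    expect_gte(sum(abs(ga_ctl - g) <= 7), 2)
  }
  # a case whose +/- 7 day window misses the control range is impossible
  bad <- tibble::tibble(subject_id = c("C1", "K1", "K2"),
                        group = c("RPL", "CONTROL", "CONTROL"),
                        ga_days = c(91L, 60L, 61L))
  expect_error(enforce_matching(bad, generator_config()), "C1")
  # matching disabled leaves the cohort untouched
  cfg_off <- generator_config(seed = 5, matching_enabled = FALSE)
  expect_identical(generate_cohort(cfg_off), generate_cohort(cfg_off))
})

test_that("dMoMs survive the matching GA resampling unchanged", {
  # controls far from the case must be moved; their dMoM must not change
  set.seed(31)
  ga <- c(70L, rep(c(36L, 38L, 40L, 42L), 5))
  dmoms <- stats::runif(length(ga), 0.5, 2)
  cohort <- tibble::tibble(
    subject_id = sprintf("M%02d", seq_along(ga)),
    group = c("RPL", rep("CONTROL", 20)),
    ga_days = ga
  )
  for (a in analytes()) {
    dom <- ga_domain(a)
    med <- daily_median(a, pmin(pmax(ga, dom[1]), dom[2]))
    cohort[[paste0("conc_", a)]] <- dmoms * med
  }
  matched <- enforce_matching(cohort, generator_config(seed = 4))
  ga_ctl <- matched$ga_days[matched$group == "CONTROL"]
  expect_gte(sum(abs(ga_ctl - 70L) <= 7), 2)
  for (a in analytes()) {
    dom <- ga_domain(a)
    med_new <- daily_median(a, pmin(pmax(matched$ga_days, dom[1]), dom[2]))
    expect_equal(matched[[paste0("conc_", a)]] / med_new, dmoms,
                 tolerance = 1e-12)
  }
  map <- attr(matched, "matching")
  expect_true(all(c("case", "control") %in% names(map)))
  expect_gte(nrow(map), 2)
})
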