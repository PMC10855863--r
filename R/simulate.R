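# Synthetic case-control cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# group-specific gestational-age sampling ranges, log-normal dMoM with
# window-specific central values per group, a common cross-analyte
# correlation of log2 dMoM, case-control gestational matching, and assay
# detection-limit floors. dMoM dispersion is calibrated so a single-marker
# classifier attains a prescribed binormal AUC.

# central dMoM per analyte / group / sampling window
.default_locations <- list(
  free_bhcg = list(
    RPL = c(early = 0.32, late = 0.05),
    CONTROL = c(early = 0.91, late = 1.2)
  ),
  pappa = list(
    RPL = c(early = 0.41, late = 0.26),
    CONTROL = c(early = 1.77, late = 1.39)
  ),
  plgf = list(
    RPL = c(early = 1.41, late = 0.6),
    CONTROL = c(early = 1.85, late = 1.28)
  )
)

# whole-range central dMoMs and single-marker AUCs used to calibrate the
# default log2-scale SDs
.whole_range_calibration <- list(
  free_bhcg = list(control = 1.13, rpl = 0.18, auc = 0.820),
  pappa = list(control = 1.66, rpl = 0.39, auc = 0.880),
  plgf = list(control = 1.52, rpl = 1.01, auc = 0.644)
)

#' Binormal inversion of an AUC into a log2-scale SD
#'
#' Under an equal-variance binormal score model, a single log2-dMoM feature
#' with group centres `log2(location_control)` and `log2(location_rpl)` and
#' common SD sigma attains `AUC = Phi(|log2(lc/lr)| / (sigma * sqrt(2)))`.
#' This inverts that relation:
#' `sigma = |log2(lc / lr)| / (sqrt(2) * qnorm(auc))`.
#'
#' @param location_control,location_rpl Positive central dMoM of each group.
#' @param target_auc Target single-marker AUC, strictly between 0.5 and 1.
#' @return The log2-scale SD (positive scalar).
#' @export
#' @examples
#' calibrate_sigma_from_auc(1.66, 0.39, 0.880)
calibrate_sigma_from_auc <- function(location_control, location_rpl, target_auc) {
  if (!is.finite(target_auc) || target_auc <= 0.5 || target_auc >= 1) {
    rlang::abort("`target_auc` must lie strictly between 0.5 and 1.")
  }
  if (location_control <= 0 || location_rpl <= 0) {
    rlang::abort("Group locations must be positive.")
  }
  if (location_control == location_rpl) {
    rlang::abort("Equal group locations cannot yield AUC > 0.5.")
  }
  abs(log2(location_control / location_rpl)) / (sqrt(2) * stats::qnorm(target_auc))
}

.default_sigmas <- function() {
  vapply(.whole_range_calibration, function(p) {
    calibrate_sigma_from_auc(p$control, p$rpl, p$auc)
  }, numeric(1))
}

#' Configuration of the synthetic cohort generator
#'
#' Collects every generator parameter with study-calibrated defaults:
#' group sizes 14 cases / 30 controls sampled at 42-91 and 35-83
#' gestational days respectively; central dMoMs per analyte, group and
#' window equal to the study's window means; log2-scale SDs calibrated by
#' [calibrate_sigma_from_auc()] from the whole-range single-marker dMoM
#' AUCs (0.820, 0.880, 0.644); a common pairwise correlation of 0.3 among
#' the three log2 dMoMs; and case-control matching (at least two controls
#' within one week of gestation per case) switched on.
#'
#' @param n_rpl,n_control Group sizes.
#' @param ga_range_rpl,ga_range_control Integer `c(min, max)` gestational-day
#'   sampling ranges per group.
#' @param dmom_location Nested list `analyte -> group -> c(early, late)` of
#'   central (geometric-mean) dMoM values.
#' @param sigma_log2 Named positive numeric vector, SD of log2 dMoM per
#'   analyte within each group.
#' @param correlation_log2 Common pairwise correlation of the analytes'
#'   log2 dMoMs, in `[0, 1)`.
#' @param matching_enabled Enforce gestational matching of controls to cases.
#' @param seed Integer RNG seed; fixed seed gives a byte-identical cohort.
#' @return A `rplmom_config` list.
#' @export
generator_config <- function(n_rpl = 14L, n_control = 30L,
                             ga_range_rpl = c(42L, 91L),
                             ga_range_control = c(35L, 83L),
                             dmom_location = .default_locations,
                             sigma_log2 = .default_sigmas(),
                             correlation_log2 = 0.3,
                             matching_enabled = TRUE,
                             seed = 1L) {
  stopifnot(
    n_rpl >= 0, n_control >= 0,
    length(ga_range_rpl) == 2, length(ga_range_control) == 2,
    ga_range_rpl[1] <= ga_range_rpl[2],
    ga_range_control[1] <= ga_range_control[2],
    all(sigma_log2 > 0),
    correlation_log2 >= 0, correlation_log2 < 1
  )
  structure(list(
    n_rpl = as.integer(n_rpl), n_control = as.integer(n_control),
    ga_range_rpl = as.integer(ga_range_rpl),
    ga_range_control = as.integer(ga_range_control),
    dmom_location = dmom_location,
    sigma_log2 = sigma_log2[analytes()],
    correlation_log2 = correlation_log2,
    matching_enabled = isTRUE(matching_enabled),
    seed = as.integer(seed)
  ), class = "rplmom_config")
}

# run code under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# concentration back-computation: dMoM times the daily median, with the
# median clamped to the analyte's reference window so that records sampled
# outside the window still carry plausible (window-edge) concentrations and
# exercise the downstream filtering
.edge_median <- function(analyte, ga_days) {
  dom <- ga_domain(analyte)
  daily_median(analyte, pmin(pmax(ga_days, dom[1]), dom[2]))
}

.truncated_normal <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out < lower)) {
    idx <- out < lower
    out[idx] <- stats::rnorm(sum(idx), mean, sd)
  }
  out
}

#' Generate a synthetic case-control cohort
#'
#' Draws, per subject: a uniform integer gestational age on the group's
#' sampling range; a trivariate normal log2-dMoM vector whose means are the
#' log2 of the group's window-specific central dMoMs, with per-analyte SDs
#' and a common pairwise correlation; concentrations back-computed as
#' dMoM times the daily median (window-edge median outside the reference
#' range) and floored at the assay detection limits; and maternal age
#' (cases: normal mean 37.2 SD 4.5; controls: normal mean 30.1 SD 7.0,
#' truncated at 16 years). With matching enabled, control gestational ages
#' are adjusted by [enforce_matching()]. Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A validated cohort tibble (schema of [read_cohort()]).
#' @export
#' @examples
#' cohort <- generate_cohort(generator_config(seed = 42))
#' dplyr::count(cohort, group)
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "rplmom_config"))
  .with_seed(config$seed, {
    n <- config$n_rpl + config$n_control
    grp <- c(rep("RPL", config$n_rpl), rep("CONTROL", config$n_control))
    ga <- c(
      sample(seq.int(config$ga_range_rpl[1], config$ga_range_rpl[2]),
             config$n_rpl, replace = TRUE),
      sample(seq.int(config$ga_range_control[1], config$ga_range_control[2]),
             config$n_control, replace = TRUE)
    )
    cohort <- tibble::tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      group = grp, ga_days = as.integer(ga)
    )
    if (config$matching_enabled && config$n_rpl > 0) {
      cohort <- enforce_matching(cohort, config, reseed = FALSE)
    }
    win <- as.character(ga_window(cohort$ga_days))
    sig <- config$sigma_log2
    R <- matrix(config$correlation_log2, 3, 3)
    diag(R) <- 1
    Sigma <- diag(sig) %*% R %*% diag(sig)
    mu <- t(vapply(seq_len(n), function(i) {
      vapply(analytes(), function(a) {
        log2(config$dmom_location[[a]][[cohort$group[i]]][[win[i]]])
      }, numeric(1))
    }, numeric(3)))
    z <- mu + MASS::mvrnorm(n, mu = rep(0, 3), Sigma = Sigma)
    for (j in seq_along(analytes())) {
      a <- analytes()[j]
      conc <- 2^z[, j] * .edge_median(a, cohort$ga_days)
      cohort[[paste0("conc_", a)]] <- pmax(conc, .detection_limits[[a]])
    }
    cohort$maternal_age_years <- ifelse(
      cohort$group == "RPL",
      .truncated_normal(n, 37.2, 4.5, 16),
      .truncated_normal(n, 30.1, 7.0, 16)
    )
    # constant demographic fills at the groups' typical values
    cohort$gravidity <- ifelse(cohort$group == "RPL", 3, 2)
    cohort$parity <- ifelse(cohort$group == "RPL", 1, 0)
    cohort$prior_losses <- ifelse(cohort$group == "RPL", 2, 0)
    validate_cohort(cohort[.cohort_cols])
  })
}

#' Enforce case-control gestational matching
#'
#' Guarantees that every case has at least two controls sampled within one
#' week (7 days) of its gestational age, by resampling the gestational ages
#' of surplus controls uniformly on the intersection of the case's +/- 7 day
#' window with the control sampling range. When the cohort carries
#' concentration columns they are rescaled by the ratio of (window-clamped)
#' daily medians so each subject's dMoM is preserved. The case-to-control
#' matching map is attached as the `"matching"` attribute.
#'
#' @param cohort A cohort tibble (at least `subject_id`, `group`, `ga_days`).
#' @param config A [generator_config()] supplying the control GA range.
#' @param reseed Seed the RNG from `config$seed` (set `FALSE` when already
#'   inside a seeded generation).
#' @return The cohort with adjusted control gestational ages.
#' @export
enforce_matching <- function(cohort, config = generator_config(), reseed = TRUE) {
  run <- function() {
    cases <- which(cohort$group == "RPL")
    controls <- which(cohort$group == "CONTROL")
    rng <- config$ga_range_control
    if (length(cases) > 0 && length(controls) < 2) {
      rlang::abort("Matching needs at least two controls.")
    }
    for (i in cases) {
      lo <- max(cohort$ga_days[i] - 7, rng[1])
      hi <- min(cohort$ga_days[i] + 7, rng[2])
      if (lo > hi) {
        rlang::abort(sprintf(
          "Case %s at %d gestational days cannot be matched: no control age in [%d, %d] intersects the control range [%d, %d].",
          cohort$subject_id[i], cohort$ga_days[i],
          cohort$ga_days[i] - 7, cohort$ga_days[i] + 7, rng[1], rng[2]))
      }
    }
    n_match <- function() vapply(cases, function(i) {
      sum(abs(cohort$ga_days[controls] - cohort$ga_days[i]) <= 7)
    }, integer(1))
    pick_day <- function(lo, hi) {
      days <- seq.int(lo, hi)
      days[sample.int(length(days), 1L)]
    }
    old_ga <- cohort$ga_days
    moves <- 0L
    repeat {
      counts <- n_match()
      deficit <- which(counts < 2)
      if (length(deficit) == 0) break
      if (moves >= 50L * length(cases)) {
        rlang::abort("Matching did not converge; widen the control GA range.")
      }
      i <- cases[deficit[1]]
      lo <- max(cohort$ga_days[i] - 7, rng[1])
      hi <- min(cohort$ga_days[i] + 7, rng[2])
      # move the control whose reassignment harms other cases least:
      # prefer controls matching no case, then those whose matched cases
      # all keep >= 2 matches after removal
      harm <- vapply(controls, function(j) {
        matched <- counts[abs(cohort$ga_days[cases] - cohort$ga_days[j]) <= 7]
        if (length(matched) == 0) 0 else 1000L - min(matched)
      }, numeric(1))
      in_window <- abs(cohort$ga_days[controls] - cohort$ga_days[i]) <= 7
      harm[in_window] <- Inf # already counted for this case
      j <- controls[which.min(harm)]
      cohort$ga_days[j] <<- as.integer(pick_day(lo, hi))
      moves <- moves + 1L
    }
    # preserve each subject's dMoM under the GA change
    moved <- which(cohort$ga_days != old_ga)
    for (a in analytes()) {
      col <- paste0("conc_", a)
      if (col %in% names(cohort)) {
        cohort[[col]][moved] <<- cohort[[col]][moved] *
          .edge_median(a, cohort$ga_days[moved]) / .edge_median(a, old_ga[moved])
      }
    }
    attr(cohort, "matching") <- purrr::map_dfr(cases, function(i) {
      tibble::tibble(
        case = cohort$subject_id[i],
        control = cohort$subject_id[controls][
          abs(cohort$ga_days[controls] - cohort$ga_days[i]) <= 7]
      )
    })
    cohort
  }
  if (reseed) .with_seed(config$seed + 1L, run()) else run()
}

#' Write a cohort CSV with a configuration sidecar
#'
#' Writes the cohort in the documented CSV schema and, when a generator
#' configuration is supplied, a YAML sidecar (`<path>.yaml`) recording the
#' fully resolved configuration including the seed.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @param config Optional [generator_config()] to record alongside.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, config = NULL) {
  readr::write_csv(cohort[, .cohort_cols], path, na = "")
  if (!is.null(config)) {
    yaml::write_yaml(lapply(unclass(config), function(x)
      if (is.list(x)) x else as.vector(x)), paste0(path, ".yaml"))
  }
  invisible(path)
}
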