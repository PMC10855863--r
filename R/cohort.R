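# Cohort schema, validation, dMoM attachment, reference-window filtering
# and gestational-week subgrouping.

.cohort_cols <- c(
  "subject_id", "group", "ga_days", "maternal_age_years", "gravidity",
  "parity", "prior_losses", "conc_free_bhcg", "conc_pappa", "conc_plgf"
)

# enrolment window: observed sampling range (35 d) through the PlGF
# reference end (98 d)
.ga_enrolment <- c(35L, 98L)

#' Read a cohort CSV
#'
#' Reads and validates a case-control cohort table. The expected header is
#' `subject_id,group,ga_days,maternal_age_years,gravidity,parity,
#' prior_losses,conc_free_bhcg,conc_pappa,conc_plgf`; missing values are
#' empty fields; `group` is `RPL` or `CONTROL` (case-insensitive).
#'
#' @param path Path to a CSV file with the documented header.
#' @return A validated cohort tibble (see [validate_cohort()]).
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(c("subject_id", "group", "ga_days"), names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Cohort file lacks required column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(.cohort_cols, names(raw))) raw[[col]] <- NA_real_
  validate_cohort(raw[.cohort_cols])
}

#' Validate a cohort table
#'
#' Checks group labels, integer gestational ages within the enrolment
#' window (35-98 d), and flags concentrations below the assay detection
#' limits (kept, but marked in `below_limit_<analyte>` columns). Violations
#' are reported with their row numbers.
#'
#' @param cohort A data frame with the cohort schema (see [read_cohort()]).
#' @return The cohort as a tibble with normalized `group` factor and
#'   below-detection-limit flag columns.
#' @export
validate_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  problems <- character(0)
  grp <- toupper(trimws(as.character(cohort$group)))
  bad_grp <- which(!grp %in% c("RPL", "CONTROL"))
  if (length(bad_grp) > 0) {
    problems <- c(problems, sprintf(
      "rows %s: group must be RPL or CONTROL", paste(bad_grp, collapse = ",")))
  }
  ga <- cohort$ga_days
  bad_ga <- which(!is.finite(ga) | ga != round(ga) |
                    ga < .ga_enrolment[1] | ga > .ga_enrolment[2])
  if (length(bad_ga) > 0) {
    problems <- c(problems, sprintf(
      "rows %s: ga_days must be whole days in [%d, %d]",
      paste(bad_ga, collapse = ","), .ga_enrolment[1], .ga_enrolment[2]))
  }
  for (a in analytes()) {
    conc <- cohort[[paste0("conc_", a)]]
    bad <- which(!is.na(conc) & conc <= 0)
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "rows %s: conc_%s must be positive when present",
        paste(bad, collapse = ","), a))
    }
  }
  if (length(problems) > 0) {
    rlang::abort(c("Invalid cohort table:", problems))
  }
  cohort$group <- factor(grp, levels = c("CONTROL", "RPL"))
  cohort$ga_days <- as.integer(ga)
  for (a in analytes()) {
    conc <- cohort[[paste0("conc_", a)]]
    cohort[[paste0("below_limit_", a)]] <-
      !is.na(conc) & conc < .detection_limits[[a]]
  }
  cohort
}

#' Gestational window of a sampling day
#'
#' Weeks are completed weeks: week w spans days `7w .. 7w+6`, so the
#' "<9 weeks" window is days <= 62 (`early`) and ">= 9 weeks" is days
#' >= 63 (`late`).
#'
#' @param ga_days Integer vector of gestational ages in days.
#' @return Factor with levels `early`, `late`.
#' @export
ga_window <- function(ga_days) {
  factor(ifelse(ga_days < 63, "early", "late"), levels = c("early", "late"))
}

#' Attach dMoM values to a cohort
#'
#' Computes, for every subject and analyte, the daily multiple of median
#' and its log2, where the subject's gestational age lies inside that
#' analyte's reference window and the concentration is present; other
#' subject-analyte pairs are kept with `in_reference_range = FALSE` and
#' missing dMoM — never clamped. The subject count is unchanged.
#'
#' @param cohort A validated cohort tibble.
#' @return A long MoM tibble: one row per subject x analyte with columns
#'   `subject_id`, `group`, `ga_days`, `window`, `analyte`,
#'   `concentration`, `in_reference_range`, `dmom`, `log2_dmom`.
#' @export
attach_moms <- function(cohort) {
  cohort <- validate_cohort(cohort)
  long <- tidyr::pivot_longer(
    cohort,
    cols = dplyr::all_of(paste0("conc_", analytes())),
    names_to = "analyte", names_prefix = "conc_",
    values_to = "concentration"
  )
  long <- dplyr::mutate(
    long,
    window = ga_window(.data$ga_days),
    below_limit = !is.na(.data$concentration) &
      .data$concentration < .detection_limits[.data$analyte],
    in_reference_range = purrr::map2_lgl(
      .data$analyte, .data$ga_days,
      function(a, g) g >= ga_domain(a)[1] && g <= ga_domain(a)[2]
    ) & !is.na(.data$concentration),
    dmom = ifelse(
      .data$in_reference_range,
      .data$concentration /
        purrr::map2_dbl(.data$analyte, .data$ga_days, function(a, g) {
          if (g >= ga_domain(a)[1] && g <= ga_domain(a)[2]) daily_median(a, g) else NA_real_
        }),
      NA_real_
    ),
    log2_dmom = log2(.data$dmom)
  )
  dplyr::select(
    long, "subject_id", "group", "ga_days", "window", "analyte",
    "concentration", "below_limit", "in_reference_range", "dmom", "log2_dmom"
  )
}

#' Filter a MoM table for an analysis
#'
#' Keeps the subjects whose dMoM is valid (concentration present and
#' gestational age inside the reference window) for *every* requested
#' analyte, restricted to those analytes — the per-analyte sample sizes of
#' a study fall out of this rule. Idempotent. Per-group retained counts are
#' attached as the `"group_counts"` attribute.
#'
#' @param moms A MoM tibble from [attach_moms()].
#' @param analytes Character vector of analyte identifiers to require.
#' @param exclude_below_limit Strict mode: also drop subjects whose
#'   concentration for a requested analyte sits below the assay detection
#'   limit (default keeps them, flagged).
#' @return The filtered MoM tibble.
#' @export
filter_for_analysis <- function(moms, analytes = rplmom::analytes(),
                                exclude_below_limit = FALSE) {
  analytes <- match_analyte(analytes)
  sub <- dplyr::filter(moms, .data$analyte %in% analytes)
  if (exclude_below_limit) {
    drop <- dplyr::filter(sub, .data$below_limit)
    sub <- dplyr::anti_join(sub, dplyr::distinct(drop, .data$subject_id),
                            by = "subject_id")
  }
  keep <- dplyr::summarise(
    dplyr::group_by(sub, .data$subject_id),
    ok = sum(.data$in_reference_range) == length(analytes), .groups = "drop"
  )
  out <- dplyr::semi_join(sub, dplyr::filter(keep, .data$ok), by = "subject_id")
  if (nrow(out) == 0) {
    rlang::abort(sprintf(
      "No subject has valid dMoMs for all of: %s.", paste(analytes, collapse = ", ")))
  }
  counts <- dplyr::count(dplyr::distinct(out, .data$subject_id, .data$group),
                         .data$group, name = "n")
  attr(out, "group_counts") <- counts
  out
}

#' Split a MoM table at nine gestational weeks
#'
#' Partitions into the early (<9 weeks, i.e. <63 d) and late (>=9 weeks)
#' sampling windows; the two parts are disjoint and their union is the
#' input.
#'
#' @inheritParams filter_for_analysis
#' @return Named list with `early` and `late` MoM tibbles.
#' @export
split_windows <- function(moms) {
  list(
    early = dplyr::filter(moms, .data$ga_days < 63),
    late = dplyr::filter(moms, .data$ga_days >= 63)
  )
}

#' Demographic summary of a cohort
#'
#' Per group: mean and SD of maternal age (years) and gestational age at
#' sampling (weeks), and median with interquartile range (type-7 linear
#' interpolation quantiles) for gravidity, parity and prior pregnancy
#' losses. SD of a single observation is reported as `NA`.
#'
#' @param cohort A validated cohort tibble.
#' @return A tibble, one row per group.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  iqr_lo <- function(x) stats::quantile(x, 0.25, names = FALSE, type = 7, na.rm = TRUE)
  iqr_hi <- function(x) stats::quantile(x, 0.75, names = FALSE, type = 7, na.rm = TRUE)
  dplyr::summarise(
    dplyr::group_by(cohort, .data$group),
    n = dplyr::n(),
    maternal_age_mean = mean(.data$maternal_age_years, na.rm = TRUE),
    maternal_age_sd = stats::sd(.data$maternal_age_years, na.rm = TRUE),
    ga_weeks_mean = mean(.data$ga_days / 7),
    ga_weeks_sd = stats::sd(.data$ga_days / 7),
    gravidity_median = stats::median(.data$gravidity, na.rm = TRUE),
    gravidity_q1 = iqr_lo(.data$gravidity),
    gravidity_q3 = iqr_hi(.data$gravidity),
    parity_median = stats::median(.data$parity, na.rm = TRUE),
    parity_q1 = iqr_lo(.data$parity),
    parity_q3 = iqr_hi(.data$parity),
    prior_losses_median = stats::median(.data$prior_losses, na.rm = TRUE),
    prior_losses_q1 = iqr_lo(.data$prior_losses),
    prior_losses_q3 = iqr_hi(.data$prior_losses),
    .groups = "drop"
  )
}
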