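# Gestational-age-specific daily-median reference curves.
#
# Each analyte's log10 daily median concentration is a published polynomial
# in x = GA - 77 (GA in days); free beta-hCG carries an extra
# 3.152 * log10(GA - 40) term, so its curve is only defined for GA > 40.
# Validity: free beta-hCG and PAPP-A on 49-97 d, PlGF on 56-98 d.

.median_curves <- list(
  free_bhcg = list(
    ga_domain = c(49L, 97L),
    f = function(ga) {
      x <- ga - 77
      -3.240 - 5.097e-2 * x - 4.480e-4 * x^2 + 3.152 * log10(ga - 40)
    }
  ),
  pappa = list(
    ga_domain = c(49L, 97L),
    f = function(ga) {
      x <- ga - 77
      0.1950 + 2.844e-2 * x - 3.522e-4 * x^2 + 1.244e-5 * x^3
    }
  ),
  plgf = list(
    ga_domain = c(56L, 98L),
    f = function(ga) {
      x <- ga - 77
      1.319 + 0.01506 * x - 1.363e-5 * x^2 - 2.336e-7 * x^3
    }
  )
)

#' Reference validity window of an analyte's daily-median curve
#'
#' @param analyte Analyte identifier (see [analytes()]).
#' @return Integer vector `c(first_day, last_day)` of gestational days for
#'   which the reference curve is valid: 49-97 for free beta-hCG and PAPP-A,
#'   56-98 for PlGF.
#' @export
#' @examples
#' ga_domain("pappa")
ga_domain <- function(analyte) {
  .median_curves[[match_analyte(analyte)]]$ga_domain
}

.check_ga <- function(analyte, ga_days) {
  if (length(ga_days) == 0L) return(integer(0))
  if (any(!is.finite(ga_days)) || any(ga_days != round(ga_days))) {
    rlang::abort("`ga_days` must be whole gestational days; convert weeks explicitly.")
  }
  dom <- ga_domain(analyte)
  out <- ga_days < dom[1] | ga_days > dom[2]
  if (any(out)) {
    rlang::abort(sprintf(
      "Gestational age %s d outside the %s reference window [%d, %d] d.",
      paste(unique(ga_days[out]), collapse = ", "),
      match_analyte(analyte), dom[1], dom[2]
    ))
  }
  invisible(ga_days)
}

#' Log10 daily-median reference concentration
#'
#' Evaluates the published gestational-age-specific log10 daily-median
#' polynomial for one analyte. Gestational age must be whole days inside the
#' analyte's reference window (see [ga_domain()]); out-of-window days raise
#' an error rather than being clamped — filter the cohort instead.
#'
#' @inheritParams ga_domain
#' @param ga_days Integer vector of gestational ages in days.
#' @return Numeric vector, log10 of the daily median concentration in the
#'   analyte's units (IU/L for free beta-hCG and PAPP-A, pg/mL for PlGF).
#' @export
#' @examples
#' log10_daily_median("pappa", 77) # 0.1950 at the curve's centring day
log10_daily_median <- function(analyte, ga_days) {
  analyte <- match_analyte(analyte)
  .check_ga(analyte, ga_days)
  .median_curves[[analyte]]$f(ga_days)
}

#' Daily-median reference concentration
#'
#' `10^log10_daily_median(...)`: the daily median concentration itself,
#' strictly positive across the reference window.
#'
#' @inheritParams log10_daily_median
#' @return Numeric vector of median concentrations in analyte units.
#' @export
#' @examples
#' daily_median("plgf", 77)
daily_median <- function(analyte, ga_days) {
  10^log10_daily_median(analyte, ga_days)
}

#' Daily multiple of median (dMoM)
#'
#' Divides a measured serum concentration by the daily median concentration
#' at the same gestational day, removing the gestational-age dependence of
#' the marker. Returns both the dMoM and its base-2 logarithm, the scale on
#' which downstream classifiers operate.
#'
#' @inheritParams log10_daily_median
#' @param concentration Positive numeric vector, measured concentration in
#'   the analyte's units. Recycled against `ga_days`.
#' @return A tibble with columns `analyte`, `ga_days`, `concentration`,
#'   `dmom` and `log2_dmom`.
#' @export
#' @examples
#' compute_dmom("pappa", daily_median("pappa", 63), 63) # dmom = 1
compute_dmom <- function(analyte, concentration, ga_days) {
  analyte <- match_analyte(analyte)
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    rlang::abort("`concentration` must be positive and finite.")
  }
  med <- daily_median(analyte, ga_days)
  n <- max(length(concentration), length(ga_days))
  dmom <- concentration / med
  tibble::tibble(
    analyte = rep_len(analyte, n),
    ga_days = as.integer(rep_len(ga_days, n)),
    concentration = rep_len(concentration, n),
    dmom = dmom,
    log2_dmom = log2(dmom)
  )
}

#' Gestational day maximizing the daily median
#'
#' Grid search over the whole integer-day reference window; ties break
#' toward the earlier day. PAPP-A and PlGF medians increase monotonically so
#' their maximum sits at the window end; the free beta-hCG median rises and
#' then falls, with an interior maximum.
#'
#' @inheritParams ga_domain
#' @return Integer gestational day.
#' @export
argmax_daily_median <- function(analyte) {
  analyte <- match_analyte(analyte)
  dom <- ga_domain(analyte)
  days <- seq.int(dom[1], dom[2])
  days[which.max(daily_median(analyte, days))]
}

#' Tabulate the daily-median reference curve
#'
#' One row per integer gestational day across the analyte's reference
#' window. Optionally written as CSV (`ga_days,median_<analyte>` header,
#' `.` decimal separator).
#'
#' @inheritParams ga_domain
#' @param path Optional file path; when given the table is also written as
#'   CSV.
#' @return A tibble with columns `ga_days` and `median_<analyte>`.
#' @export
#' @examples
#' head(median_table("plgf"))
median_table <- function(analyte, path = NULL) {
  analyte <- match_analyte(analyte)
  dom <- ga_domain(analyte)
  days <- seq.int(dom[1], dom[2])
  out <- tibble::tibble(ga_days = days, median = daily_median(analyte, days))
  names(out)[2] <- paste0("median_", analyte)
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
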