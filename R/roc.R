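# ROC machinery: empirical curves, trapezoidal AUC, sensitivity at fixed
# false-positive rate, and likelihood ratios.

#' Empirical ROC curve
#'
#' Standard threshold sweep over the unique score values, higher scores
#' being more case-like; tied scores are grouped at a single threshold.
#' The curve always starts at (0, 0) and ends at (1, 1).
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (1/TRUE = case, 0/FALSE = control); both
#'   classes must be present.
#' @return A tibble with increasing `fpr` and `tpr` columns.
#' @export
#' @examples
#' empirical_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
empirical_roc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    rlang::abort("Both classes must be present to build a ROC curve.")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  # group ties: cumulative counts at the last index of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  tibble::tibble(
    fpr = c(0, fp / sum(1 - y), 1),
    tpr = c(0, tp / sum(y), 1)
  ) |> dplyr::distinct()
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A tibble with `fpr` and `tpr` columns (as from
#'   [empirical_roc()]).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Sensitivity at a fixed false-positive rate
#'
#' Linear interpolation of the curve's TPR at the requested FPR.
#'
#' @param roc A ROC tibble (`fpr`, `tpr`) or an averaged ROC object from
#'   [run_repeated_cv()] (its mean curve is used).
#' @param fpr False-positive rate(s) in `[0, 1]`.
#' @return Interpolated TPR value(s).
#' @export
tpr_at_fpr <- function(roc, fpr) {
  stopifnot(all(fpr >= 0 & fpr <= 1))
  if (inherits(roc, "rplmom_avg_roc")) {
    roc <- tibble::tibble(fpr = roc$fpr_grid, tpr = roc$mean_tpr)
  }
  stats::approx(roc$fpr, roc$tpr, xout = fpr, ties = max, rule = 2)$y
}

#' Likelihood ratios at an operating point
#'
#' `LR+ = TPR / FPR` and `LR- = (1 - TPR) / (1 - FPR)` for a classifier
#' operated at the given false-positive rate.
#'
#' @param tpr Sensitivity in `[0, 1]`.
#' @param fpr False-positive rate, strictly between 0 and 1.
#' @return A tibble with `lr_pos` and `lr_neg`.
#' @export
#' @examples
#' likelihood_ratios(1.0, 0.10) # LR+ 10, LR- 0
likelihood_ratios <- function(tpr, fpr) {
  stopifnot(all(tpr >= 0 & tpr <= 1))
  if (any(fpr <= 0 | fpr >= 1)) {
    rlang::abort("Likelihood ratios are undefined at FPR of exactly 0 or 1.")
  }
  tibble::tibble(lr_pos = tpr / fpr, lr_neg = (1 - tpr) / (1 - fpr))
}
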