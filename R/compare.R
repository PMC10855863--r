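# Two-group comparisons of concentrations and dMoMs.

#' Compare two groups of measurements
#'
#' Two-sided comparison of case and control values. The default is the
#' Mann-Whitney (Wilcoxon rank-sum) test, exact by full enumeration of the
#' U null distribution when the combined sample size is at most 25 and the
#' data carry no ties, and a normal approximation with continuity
#' correction otherwise (ties always use the approximation, with a
#' warning from the underlying test). `"welch_t"` gives the
#' unequal-variance t test.
#'
#' @param values_rpl,values_control Non-empty numeric vectors.
#' @param method `"mann_whitney"` (default) or `"welch_t"`.
#' @return A one-row tibble: group means, medians, sizes, `p_value`,
#'   `statistic` and `test_name`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6, 7))
compare_groups <- function(values_rpl, values_control,
                           method = c("mann_whitney", "welch_t")) {
  method <- match.arg(method)
  if (length(values_rpl) == 0 || length(values_control) == 0) {
    rlang::abort("Both groups must be non-empty.")
  }
  if (method == "mann_whitney") {
    n <- length(values_rpl) + length(values_control)
    has_ties <- anyDuplicated(c(values_rpl, values_control)) > 0
    exact <- n <= 25 && !has_ties
    ht <- suppressWarnings(stats::wilcox.test(
      values_rpl, values_control, exact = exact, correct = TRUE))
    test_name <- if (exact) "mann_whitney_exact" else "mann_whitney_normal_approx"
    if (is.nan(ht$p.value)) {
      # every observation tied: no evidence against the null
      rlang::warn("All values tied across groups; reporting p = 1.")
      ht$p.value <- 1
    }
  } else {
    if (length(values_rpl) < 2 || length(values_control) < 2) {
      rlang::abort("Welch's t test needs at least two values per group.")
    }
    ht <- stats::t.test(values_rpl, values_control)
    test_name <- "welch_t"
  }
  tibble::tibble(
    n_rpl = length(values_rpl), n_control = length(values_control),
    mean_rpl = mean(values_rpl), mean_control = mean(values_control),
    median_rpl = stats::median(values_rpl),
    median_control = stats::median(values_control),
    statistic = unname(ht$statistic),
    p_value = min(ht$p.value, 1),
    test_name = test_name
  )
}

#' Significance stars
#'
#' Maps a p-value to the conventional label: `ns` for p > 0.05, `*` for
#' p < 0.05, `**` for p < 0.01, `***` for p < 0.001. Boundary values map to
#' the less significant label.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of labels.
#' @export
#' @examples
#' stars(c(0.2, 0.03, 0.0009, 0.05))
stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare groups for every analyte, scale and window
#'
#' Runs [compare_groups()] on concentrations and dMoMs of each analyte in
#' the whole cohort and in the early (<9 weeks) and late (>=9 weeks)
#' windows, using only subjects valid for that analyte.
#'
#' @param moms A MoM tibble from [attach_moms()].
#' @param method Passed to [compare_groups()].
#' @return A tibble, one row per analyte x scale x window, with the
#'   [compare_groups()] columns plus `analyte`, `scale`, `window` and
#'   `significance`.
#' @export
compare_all <- function(moms, method = c("mann_whitney", "welch_t")) {
  method <- match.arg(method)
  grids <- tidyr::expand_grid(
    analyte = analytes(),
    scale = c("concentration", "dmom"),
    win = c("all", "early", "late")
  )
  purrr::pmap_dfr(grids, function(analyte, scale, win) {
    sub <- dplyr::filter(moms, .data$analyte == !!analyte, .data$in_reference_range)
    if (win != "all") sub <- dplyr::filter(sub, .data$window == win)
    vals <- if (scale == "concentration") sub$concentration else sub$dmom
    rpl <- vals[sub$group == "RPL"]
    ctl <- vals[sub$group == "CONTROL"]
    if (length(rpl) == 0 || length(ctl) == 0) return(NULL)
    res <- compare_groups(rpl, ctl, method = method)
    dplyr::bind_cols(
      tibble::tibble(analyte = analyte, scale = scale, window = win),
      res,
      tibble::tibble(significance = stars(res$p_value))
    )
  })
}
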