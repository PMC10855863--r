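# ggplot2 displays for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an averaged ROC curve
#'
#' Mean cross-validated ROC with a +/- 1 SD sensitivity ribbon and the
#' chance diagonal.
#'
#' @param object An `rplmom_avg_roc` from [run_repeated_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rplmom_avg_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$mean_tpr)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$mean_tpr - .data$sd_tpr, 0),
                   ymax = pmin(.data$mean_tpr + .data$sd_tpr, 1)),
      fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate", y = "True-positive rate (sensitivity)",
      title = sprintf("Averaged ROC (%d x %d-fold CV), AUC = %.3f",
                      object$n_runs, object$k, object$auc)) +
    ggplot2::theme_minimal()
}

#' Box plots of dMoM values by group
#'
#' One panel per analyte, dMoM on a log2 axis, cases versus controls;
#' mirrors the standard presentation of MoM group differences.
#'
#' @param moms A MoM tibble from [attach_moms()].
#' @return A ggplot.
#' @export
plot_dmom_box <- function(moms) {
  df <- dplyr::filter(moms, .data$in_reference_range)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$dmom,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, show.legend = FALSE) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "dMoM") +
    ggplot2::theme_minimal()
}

#' Daily-median reference curves
#'
#' The three analytes' daily median concentrations over their reference
#' windows, on a log10 axis.
#'
#' @return A ggplot.
#' @export
plot_median_curves <- function() {
  df <- purrr::map_dfr(analytes(), function(a) {
    tab <- median_table(a)
    tibble::tibble(analyte = a, ga_days = tab$ga_days, median = tab[[2]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ga_days, y = .data$median)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "Gestational age (days)",
                  y = "Daily median concentration") +
    ggplot2::theme_minimal()
}
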