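# Repeated stratified cross-validation with ROC averaging across runs.

.default_fpr_grid <- seq(0, 1, by = 0.01)

#' Repeated stratified k-fold cross-validation of a logistic classifier
#'
#' Runs `n_runs` independent stratified random `k`-fold cross-validations.
#' In each run, every fold's model is fitted on the remaining folds (the
#' standardization statistics come from the training folds only, unless
#' `scale_mode = "global"`), the held-out fold is scored, and the run's
#' pooled out-of-fold scores form one ROC curve. Each run's TPR is
#' interpolated onto a common FPR grid (0 to 1 in steps of 0.01); the
#' averaged curve is the pointwise mean (and SD) of the runs' sensitivities,
#' and the reported AUC is the arithmetic mean of the runs' trapezoidal
#' AUCs. Runs whose random split leaves a training set single-class are
#' redrawn with the next seed.
#'
#' @inheritParams fit_logistic
#' @param n_runs Number of repeated cross-validation runs (default 50).
#' @param k Number of folds (default 5); lowered to the minority-class
#'   count with a warning when that count is smaller.
#' @param seed Integer seed; the full procedure is deterministic given it.
#' @param scale_mode `"fold"` (standardize within training folds; default)
#'   or `"global"` (standardize once on the full data set).
#' @return An object of class `rplmom_avg_roc`: `fpr_grid`, `mean_tpr`,
#'   `sd_tpr`, `per_run_auc`, `auc` (mean of per-run AUCs),
#'   `auc_of_mean_curve`, and the run settings.
#' @export
#' @examples
#' x <- matrix(c(rnorm(40, 1), rnorm(40)), ncol = 1)
#' y <- rep(c(1, 0), each = 40)
#' cv <- run_repeated_cv(x, y, n_runs = 5, seed = 7)
#' cv$auc
run_repeated_cv <- function(features, labels, n_runs = 50L, k = 5L,
                            seed = 1L, penalty = 0,
                            scale_mode = c("fold", "global")) {
  scale_mode <- match.arg(scale_mode)
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  n_min <- min(sum(y == 1), sum(y == 0))
  if (n_min < 1) rlang::abort("Both classes must be present.")
  if (n_min < k) {
    rlang::warn(sprintf("Minority class has %d members; lowering k from %d to %d.",
                        n_min, k, n_min))
    k <- n_min
  }
  scaler <- if (scale_mode == "global") {
    list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
  } else NULL
  grid <- .default_fpr_grid
  tpr_mat <- matrix(NA_real_, nrow = n_runs, ncol = length(grid))
  per_run_auc <- numeric(n_runs)
  # stratified fold assignment: shuffle within class, deal round-robin
  make_folds <- function() {
    folds <- integer(length(y))
    for (cls in c(0, 1)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  }
  extra_seed <- 0L
  for (r in seq_len(n_runs)) {
    repeat {
      folds <- .with_seed(seed + r + extra_seed, make_folds())
      ok <- all(vapply(seq_len(k), function(f) {
        length(unique(y[folds != f])) == 2
      }, logical(1)))
      if (ok) break
      extra_seed <- extra_seed + n_runs
      message(sprintf("Run %d produced a single-class training set; redrawing split.", r))
    }
    scores <- numeric(length(y))
    for (f in seq_len(k)) {
      train <- folds != f
      fit <- fit_logistic(x[train, , drop = FALSE], y[train],
                          penalty = penalty, scaler = scaler)
      scores[!train] <- predict_probability(fit, x[!train, , drop = FALSE])
    }
    roc <- empirical_roc(scores, y)
    per_run_auc[r] <- roc_auc(roc)
    tpr_mat[r, ] <- stats::approx(roc$fpr, roc$tpr, xout = grid,
                                  ties = max, rule = 2)$y
  }
  mean_tpr <- cummax(colMeans(tpr_mat)) # monotone after averaging
  sd_tpr <- apply(tpr_mat, 2, stats::sd)
  structure(list(
    fpr_grid = grid,
    mean_tpr = mean_tpr,
    sd_tpr = sd_tpr,
    per_run_auc = per_run_auc,
    auc = mean(per_run_auc),
    auc_of_mean_curve = sum(diff(grid) * (utils::head(mean_tpr, -1) +
                                            utils::tail(mean_tpr, -1)) / 2),
    n_runs = n_runs, k = k, n = length(y), seed = seed,
    feature_names = colnames(x), penalty = penalty, scale_mode = scale_mode
  ), class = "rplmom_avg_roc")
}

#' @export
print.rplmom_avg_roc <- function(x, ...) {
  cat(sprintf(
    "Averaged ROC over %d runs of %d-fold CV (n = %d; features: %s)\n",
    x$n_runs, x$k, x$n, paste(x$feature_names, collapse = ", ")))
  cat(sprintf("  mean AUC: %.3f (per-run range %.3f-%.3f)\n",
              x$auc, min(x$per_run_auc), max(x$per_run_auc)))
  cat(sprintf("  TPR at 5%% FPR: %.2f%%; at 10%% FPR: %.2f%%\n",
              100 * tpr_at_fpr(x, 0.05), 100 * tpr_at_fpr(x, 0.10)))
  invisible(x)
}

#' @export
tidy.rplmom_avg_roc <- function(x, ...) {
  tibble::tibble(fpr = x$fpr_grid, mean_tpr = x$mean_tpr, sd_tpr = x$sd_tpr)
}

#' @export
glance.rplmom_avg_roc <- function(x, ...) {
  discrimination_report(x)
}

#' Summarize an averaged ROC as a discrimination report row
#'
#' The table-style summary of a cross-validated classifier: mean AUC,
#' sensitivity at 5% and 10% false-positive rates, and the corresponding
#' positive and negative likelihood ratios.
#'
#' @param cv An `rplmom_avg_roc` from [run_repeated_cv()].
#' @return A one-row tibble: `auc`, `auc_of_mean_curve`, `tpr_at_5`,
#'   `tpr_at_10` (proportions), `lr_pos_5`, `lr_neg_5`, `lr_pos_10`,
#'   `lr_neg_10`.
#' @export
discrimination_report <- function(cv) {
  stopifnot(inherits(cv, "rplmom_avg_roc"))
  t5 <- tpr_at_fpr(cv, 0.05)
  t10 <- tpr_at_fpr(cv, 0.10)
  lr5 <- likelihood_ratios(t5, 0.05)
  lr10 <- likelihood_ratios(t10, 0.10)
  tibble::tibble(
    auc = cv$auc, auc_of_mean_curve = cv$auc_of_mean_curve,
    tpr_at_5 = t5, tpr_at_10 = t10,
    lr_pos_5 = lr5$lr_pos, lr_neg_5 = lr5$lr_neg,
    lr_pos_10 = lr10$lr_pos, lr_neg_10 = lr10$lr_neg
  )
}

#' Cross-validated discrimination of an analyte panel
#'
#' End-to-end evaluation of one feature set on one scale and window:
#' filters the MoM table to subjects valid for every requested analyte
#' (and the window), builds the log2 feature matrix, runs
#' [run_repeated_cv()], and summarizes it with [discrimination_report()].
#'
#' @param moms A MoM tibble from [attach_moms()].
#' @param analytes Character vector of analytes forming the panel.
#' @param scale `"dmom"` (log2 dMoM features) or `"concentration"`
#'   (log2 concentration features).
#' @param window `"all"`, `"early"` (<9 weeks) or `"late"` (>=9 weeks).
#' @inheritParams run_repeated_cv
#' @return A one-row tibble describing the panel (`analytes`, `scale`,
#'   `window`, per-group n) joined with the [discrimination_report()]
#'   columns; the full `rplmom_avg_roc` is attached as the `"roc"`
#'   attribute.
#' @export
evaluate_discrimination <- function(moms, analytes = rplmom::analytes(),
                                    scale = c("dmom", "concentration"),
                                    window = c("all", "early", "late"),
                                    n_runs = 50L, k = 5L, seed = 1L,
                                    penalty = 0) {
  scale <- match.arg(scale)
  window <- match.arg(window)
  analytes <- match_analyte(analytes)
  sub <- moms
  if (window != "all") sub <- dplyr::filter(sub, .data$window == !!window)
  sub <- filter_for_analysis(sub, analytes)
  wide <- tidyr::pivot_wider(
    dplyr::select(sub, "subject_id", "group", "analyte",
                  value = if (scale == "dmom") "log2_dmom" else "concentration"),
    names_from = "analyte", values_from = "value"
  )
  x <- as.matrix(wide[, analytes, drop = FALSE])
  if (scale == "concentration") x <- log2(x)
  y <- as.numeric(wide$group == "RPL")
  cv <- run_repeated_cv(x, y, n_runs = n_runs, k = k, seed = seed,
                        penalty = penalty)
  out <- dplyr::bind_cols(
    tibble::tibble(
      features = paste(analytes, collapse = "+"),
      scale = scale, window = window,
      n_rpl = sum(y == 1), n_control = sum(y == 0)
    ),
    discrimination_report(cv)
  )
  attr(out, "roc") <- cv
  out
}
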