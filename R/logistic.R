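# Logistic-regression classifier on standardized log2-dMoM features, and
# the fixed published models evaluated directly on log2 inputs.

#' Fit a logistic classifier on standardized features
#'
#' Standardizes each feature to zero mean and unit SD (statistics taken
#' from the supplied data and stored in the model's scaler) and maximizes
#' the Bernoulli log-likelihood — optionally ridge-penalized — by iteratively
#' reweighted least squares, stopping when the gradient's max-norm falls
#' below `1e-8` or after 100 iterations. Complete separation under an
#' unpenalized fit is detected (non-convergence with diverging
#' coefficients) and flagged in `$separation`, not silently shrunk.
#'
#' @param features Numeric matrix or data frame, one column per feature
#'   (log2 dMoM or log2 concentration values).
#' @param labels Binary vector (1/TRUE = case, 0/FALSE = control).
#' @param penalty Ridge penalty lambda on the standardized coefficients
#'   (intercept unpenalized); `0` for plain maximum likelihood.
#' @param scaler Optional externally computed standardization,
#'   `list(mean =, sd =)` per feature; by default the statistics come from
#'   `features` itself.
#' @return An object of class `rplmom_logistic` with elements `intercept`,
#'   `coefficients`, `scaler` (per-feature mean and SD), `penalty`,
#'   `converged`, `separation`.
#' @export
#' @examples
#' x <- matrix(rnorm(100), ncol = 1)
#' y <- rbinom(100, 1, plogis(-0.5 + 1.5 * x[, 1]))
#' fit_logistic(x, y)
fit_logistic <- function(features, labels, penalty = 0, scaler = NULL) {
  x <- as.matrix(features)
  if (ncol(x) > 0L && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  y <- as.numeric(labels)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y), penalty >= 0)
  if (length(unique(y)) < 2) {
    rlang::abort("Labels contain a single class; cannot fit a classifier.")
  }
  if (ncol(x) == 0L) { # intercept-only null model
    return(structure(list(
      feature_names = character(0),
      intercept = stats::qlogis(mean(y)),
      coefficients = numeric(0),
      scaler = list(mean = numeric(0), sd = numeric(0)),
      penalty = penalty, converged = TRUE, separation = FALSE
    ), class = "rplmom_logistic"))
  }
  if (is.null(scaler)) {
    mu <- colMeans(x)
    sd_ <- apply(x, 2, stats::sd)
  } else {
    mu <- scaler$mean
    sd_ <- scaler$sd
  }
  if (any(sd_ == 0)) {
    rlang::abort(sprintf("Zero-variance feature(s): %s.",
                         paste(colnames(x)[sd_ == 0], collapse = ", ")))
  }
  xs <- scale(x, center = mu, scale = sd_)
  X <- cbind(`(intercept)` = 1, xs)
  p <- ncol(X)
  pen <- c(0, rep(penalty, p - 1L)) # intercept unpenalized
  beta <- numeric(p)
  converged <- FALSE
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% beta)
    prob <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - prob)) - pen * beta
    if (max(abs(grad)) <= 1e-8) { converged <- TRUE; break }
    w <- pmax(prob * (1 - prob), 1e-10)
    H <- crossprod(X, X * w) + diag(pen, p)
    beta <- beta + solve(H, grad)
  }
  # under complete separation the likelihood has no maximum: IRLS either
  # stalls or "converges" with saturated probabilities and diverging
  # standardized coefficients
  separation <- penalty == 0 && (!converged || max(abs(beta[-1])) > 10)
  structure(list(
    feature_names = colnames(x),
    intercept = unname(beta[1]),
    coefficients = stats::setNames(beta[-1], colnames(x)),
    scaler = list(mean = mu, sd = sd_),
    penalty = penalty,
    converged = converged,
    separation = separation
  ), class = "rplmom_logistic")
}

#' Predicted case probability
#'
#' Applies the model's stored standardization to new features and returns
#' the logistic probability of being a case.
#'
#' @param model A fitted [fit_logistic()] model.
#' @param features Numeric matrix/data frame with the model's feature
#'   columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(model, "rplmom_logistic"))
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- model$feature_names
  if (!all(model$feature_names %in% colnames(x))) {
    rlang::abort("Feature columns do not match the model's features.")
  }
  x <- x[, model$feature_names, drop = FALSE]
  xs <- scale(x, center = model$scaler$mean, scale = model$scaler$sd)
  stats::plogis(model$intercept + drop(xs %*% model$coefficients))
}

#' @export
print.rplmom_logistic <- function(x, ...) {
  cat("Logistic classifier on standardized features\n")
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  for (nm in x$feature_names) {
    cat(sprintf("  %s: %.4f\n", nm, x$coefficients[[nm]]))
  }
  if (x$separation) cat("  (complete separation detected; coefficients diverge)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rplmom_logistic <- function(x, ...) {
  tibble::tibble(
    term = c("(intercept)", x$feature_names),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.rplmom_logistic <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    penalty = x$penalty,
    converged = x$converged,
    separation = x$separation
  )
}

# published fixed-coefficient models: intercept + coefficients applied
# directly to log2 of the raw inputs (no standardization)
.printed_models <- list(
  conc_free_bhcg = list(intercept = -0.894, coef = c(free_bhcg = -1.432)),
  conc_pappa = list(intercept = -0.865, coef = c(pappa = -0.781)),
  conc_plgf = list(intercept = -0.607, coef = c(plgf = -0.468)),
  conc_free_bhcg_pappa = list(
    intercept = -0.946, coef = c(free_bhcg = -1.283, pappa = -0.377)),
  conc_free_bhcg_plgf = list(
    intercept = -0.646, coef = c(free_bhcg = -1.414, plgf = -0.0826)),
  conc_pappa_plgf = list(
    intercept = -0.672, coef = c(pappa = -0.795, plgf = -0.111)),
  conc_free_bhcg_pappa_plgf = list(
    intercept = -0.695, coef = c(free_bhcg = -1.287, pappa = -0.542, plgf = 0.134)),
  dmom_free_bhcg = list(intercept = -0.740, coef = c(free_bhcg = -1.552)),
  dmom_pappa = list(intercept = -0.842, coef = c(pappa = -1.782)),
  dmom_plgf = list(intercept = -0.379, coef = c(plgf = -0.720)),
  dmom_free_bhcg_pappa = list(
    intercept = -0.783, coef = c(free_bhcg = -0.867, pappa = -1.260)),
  dmom_free_bhcg_plgf = list(
    intercept = -0.319, coef = c(free_bhcg = -1.314, plgf = -0.292)),
  dmom_pappa_plgf = list(
    intercept = -0.381, coef = c(pappa = -1.697, plgf = -0.075)),
  dmom_free_bhcg_pappa_plgf = list(
    intercept = -0.283, coef = c(free_bhcg = -0.763, pappa = -1.338, plgf = 0.0215))
)

#' Published discriminative models
#'
#' The fixed-coefficient logistic models published for single markers and
#' marker combinations on two scales: raw concentrations (`conc_*`) and
#' daily MoM values (`dmom_*`). Each model is an affine expression in the
#' log2 of its inputs giving the log-odds of recurrent pregnancy loss.
#'
#' @return A tibble with `model_id`, `scale`, `term` and `estimate` (the
#'   intercept appears as term `"(intercept)"`).
#' @export
#' @examples
#' printed_models()
printed_models <- function() {
  purrr::imap_dfr(.printed_models, function(m, id) {
    tibble::tibble(
      model_id = id,
      scale = if (startsWith(id, "dmom")) "dmom" else "concentration",
      term = c("(intercept)", names(m$coef)),
      estimate = c(m$intercept, unname(m$coef))
    )
  })
}

#' Evaluate a published model
#'
#' Computes the log-odds of recurrent pregnancy loss from one of the
#' published fixed-coefficient models: the printed affine expression
#' evaluated at the log2 of the supplied positive inputs (dMoM values for
#' `dmom_*` models, concentrations in analyte units for `conc_*` models).
#' No standardization is applied.
#'
#' @param model_id One of the identifiers in [printed_models()].
#' @param values Named positive numeric vector/list covering the model's
#'   analytes (names as in [analytes()]).
#' @return The linear predictor (log-odds), a numeric scalar or vector.
#' @export
#' @examples
#' evaluate_printed_model("dmom_free_bhcg", c(free_bhcg = 1)) # -0.740
evaluate_printed_model <- function(model_id, values) {
  if (!model_id %in% names(.printed_models)) {
    rlang::abort(sprintf("Unknown model_id '%s'; see printed_models().", model_id))
  }
  m <- .printed_models[[model_id]]
  values <- unlist(values)
  names(values) <- match_analyte(names(values))
  missing <- setdiff(names(m$coef), names(values))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Missing value(s) for: %s.", paste(missing, collapse = ", ")))
  }
  if (any(values <= 0)) rlang::abort("Inputs must be positive (log2 is taken).")
  vals <- rbind(values[names(m$coef)])
  drop(m$intercept + log2(vals) %*% m$coef)
}
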