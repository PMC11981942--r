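# Noise-ceiling-corrected predictive accuracy over repeated test stimuli.

# population (1/T) variance and covariance, used throughout: the ceiling
# estimator is convention-sensitive at small T, so the convention is fixed
# and tested.
var_pop <- function(x) mean((x - mean(x))^2)
cov_pop <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

#' Noise-ceiling-corrected correlation metrics for one neuron
#'
#' Computes `CC_abs`, the Pearson correlation between the predicted trace and
#' the trial-averaged observed trace; `CC_max`, the ceiling
#' `sqrt((N Var(ybar) - mean_i Var(y_i)) / ((N - 1) Var(ybar)))` achievable by
#' a perfect model given trial-to-trial variability and `N` repeats; and
#' their ratio `CC_norm = CC_abs / CC_max`. Variances use the population
#' (1/T) convention; `mean Var(y)` is the across-trial average of each
#' trial's variance over time. Neurons with fewer than 2 repeats, zero
#' signal variance, or a non-positive ceiling radicand are flagged invalid
#' (`cc_max`/`cc_norm` = NA), not clamped.
#'
#' @param pred Numeric length-T predicted response trace.
#' @param trials `N x T` matrix of observed responses to identical repeats.
#' @return List with `cc_abs`, `cc_max`, `cc_norm`, `valid`.
#' @export
cc_metrics <- function(pred, trials) {
  trials <- as.matrix(trials)
  N <- nrow(trials)
  if (ncol(trials) != length(pred)) {
    stop("prediction and trials must share the time axis", call. = FALSE)
  }
  ybar <- colMeans(trials)
  v_ybar <- var_pop(ybar)
  v_pred <- var_pop(pred)
  cc_abs <- if (v_ybar > 0 && v_pred > 0) {
    cov_pop(pred, ybar) / sqrt(v_pred * v_ybar)
  } else NA_real_
  if (N < 2 || v_ybar <= 0) {
    return(list(cc_abs = cc_abs, cc_max = NA_real_, cc_norm = NA_real_, valid = FALSE))
  }
  mean_var <- mean(apply(trials, 1, var_pop))
  radicand <- (N * v_ybar - mean_var) / ((N - 1) * v_ybar)
  if (!is.finite(radicand) || radicand <= 0) {
    return(list(cc_abs = cc_abs, cc_max = NA_real_, cc_norm = NA_real_, valid = FALSE))
  }
  cc_max <- sqrt(radicand)
  list(cc_abs = cc_abs, cc_max = cc_max,
       cc_norm = if (is.na(cc_abs)) NA_real_ else cc_abs / cc_max,
       valid = is.finite(cc_abs))
}

#' Per-session evaluation of predictions against repeated trials
#'
#' @param pred `T x N` matrix of predicted responses.
#' @param trials_list List of length N; element n is the `R x T` repeat matrix
#'   for neuron n.
#' @return Data frame with one row per neuron: `neuron`, `cc_abs`, `cc_max`,
#'   `cc_norm`, `valid`.
#' @export
evaluate_predictions <- function(pred, trials_list) {
  stopifnot(ncol(pred) == length(trials_list))
  rows <- lapply(seq_along(trials_list), function(n) {
    m <- cc_metrics(pred[, n], trials_list[[n]])
    data.frame(neuron = n, cc_abs = m$cc_abs, cc_max = m$cc_max,
               cc_norm = m$cc_norm, valid = m$valid)
  })
  do.call(rbind, rows)
}

#' Session-level summary of per-neuron metrics
#'
#' Median `CC_norm` over valid neurons; invalid neurons (undefined ceiling)
#' are excluded from all quantiles and counted.
#'
#' @param metrics Data frame from [evaluate_predictions()] (or any frame with
#'   `cc_norm` and `valid` columns).
#' @return List with `median_cc_norm`, `median_cc_abs`, `n_valid`,
#'   `n_invalid`, and the quartiles of `cc_norm`.
#' @export
session_summary <- function(metrics) {
  ok <- which(metrics$valid & is.finite(metrics$cc_norm))
  if (length(ok) == 0) stop("no valid neurons to summarize", call. = FALSE)
  qs <- stats::quantile(metrics$cc_norm[ok], c(0.25, 0.5, 0.75), names = FALSE)
  list(median_cc_norm = stats::median(metrics$cc_norm[ok]),
       median_cc_abs = stats::median(metrics$cc_abs[ok]),
       n_valid = length(ok), n_invalid = nrow(metrics) - length(ok),
       cc_norm_q25 = qs[1], cc_norm_q50 = qs[2], cc_norm_q75 = qs[3])
}
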