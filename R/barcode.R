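# Functional barcodes: per-neuron readout feature-weight vectors used to
# predict categorical anatomy (visual area, cell type) via L2-regularized
# multinomial logistic regression with nested cross-validation, plus a
# likelihood-ratio control for cortical-depth confounds.

#' Balanced accuracy
#'
#' Mean of per-class recall over the classes present in `truth`; insensitive
#' to class imbalance.
#'
#' @param truth,pred Factors or character vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(truth))
  mean(vapply(classes, function(k) mean(pred[truth == k] == k), 0))
}

#' Row-normalized confusion matrix
#'
#' Rows are true classes and sum to 1; the diagonal holds per-class recall.
#'
#' @param truth,pred Factors or character vectors.
#' @return Matrix `K x K` with dimnames `(truth, pred)`.
#' @export
confusion_matrix <- function(truth, pred) {
  classes <- sort(unique(as.character(truth)))
  m <- table(factor(truth, classes), factor(pred, classes))
  m <- sweep(unclass(m), 1, pmax(rowSums(m), 1), "/")
  names(dimnames(m)) <- c("truth", "pred")
  m
}

# stratified fold assignment (one fold id per row), deterministic given the
# RNG state
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has %d members, fewer than %d folds",
                   cl, length(idx), k), call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_l2_multinomial <- function(x, y, lambda_grid) {
  glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                 lambda = sort(lambda_grid, decreasing = TRUE),
                 standardize = TRUE)
}

predict_l2_multinomial <- function(fit, x, lambda) {
  cls <- predict(fit, newx = x, s = lambda, type = "class", exact = FALSE)
  as.character(cls[, 1])
}

#' Nested cross-validated multinomial logistic classification
#'
#' Outer stratified K-fold CV estimates held-out performance; within each
#' outer training set an inner stratified K-fold CV selects the L2
#' regularization strength by balanced accuracy (ties to the stronger
#' penalty). Held-out predictions from all outer folds are concatenated
#' before computing the final balanced accuracy and row-normalized confusion
#' matrix, so inner selection never sees outer test rows.
#'
#' @param x `n x C` feature matrix (e.g. readout weight barcodes).
#' @param y Length-n class labels (>= 2 classes, each with at least
#'   `outer_folds` members).
#' @param outer_folds,inner_folds Fold counts (default 10 and 10).
#' @param l2_grid L2 penalty grid (default `10^(-3:3)`).
#' @param seed RNG seed controlling the fold assignments.
#' @return An object of class `barcode_cv_report`: `balanced_accuracy`,
#'   `confusion` (rows sum to 1), `predictions` (per-row held-out label),
#'   `fold` (outer fold of each row), `lambda_per_fold`.
#' @export
nested_cv_logistic <- function(x, y, outer_folds = 10L, inner_folds = 10L,
                               l2_grid = 10^seq(-3, 3, by = 1), seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("need at least 2 classes", call. = FALSE)
  with_preserved_seed(seed, {
    outer <- stratified_folds(y, outer_folds)
    pred <- character(length(y))
    lambda_sel <- numeric(outer_folds)
    for (f in seq_len(outer_folds)) {
      tr <- which(outer != f)
      te <- which(outer == f)
      inner <- stratified_folds(y[tr], inner_folds)
      score <- matrix(0, inner_folds, length(l2_grid))
      for (g in seq_len(inner_folds)) {
        itr <- tr[inner != g]
        iva <- tr[inner == g]
        fit <- fit_l2_multinomial(x[itr, , drop = FALSE], y[itr], l2_grid)
        for (li in seq_along(l2_grid)) {
          p <- predict_l2_multinomial(fit, x[iva, , drop = FALSE], l2_grid[li])
          score[g, li] <- balanced_accuracy(y[iva], p)
        }
      }
      mean_score <- colMeans(score)
      best <- which(mean_score >= max(mean_score) - 1e-12)
      li <- best[which.max(l2_grid[best])] # tie -> stronger penalty
      lambda_sel[f] <- l2_grid[li]
      fit <- fit_l2_multinomial(x[tr, , drop = FALSE], y[tr], l2_grid)
      pred[te] <- predict_l2_multinomial(fit, x[te, , drop = FALSE], l2_grid[li])
    }
    structure(list(balanced_accuracy = balanced_accuracy(y, pred),
                   confusion = confusion_matrix(y, pred),
                   predictions = pred, fold = outer,
                   lambda_per_fold = lambda_sel),
              class = "barcode_cv_report")
  })
}

#' Deduplicate repeatedly scanned neurons
#'
#' When the same neuron appears in several scans, keep the occurrence with
#' the highest `cc_max` so each neuron contributes one barcode.
#'
#' @param table Data frame with columns `neuron_id` and `cc_max` (other
#'   columns carried along).
#' @return The deduplicated data frame.
#' @export
deduplicate_barcodes <- function(table) {
  ord <- order(table$neuron_id, -table$cc_max)
  t2 <- table[ord, , drop = FALSE]
  t2[!duplicated(t2$neuron_id), , drop = FALSE]
}

multinom_loglik <- function(x, y) {
  df <- data.frame(y = factor(y))
  fit <- nnet::multinom(y ~ ., data = cbind(df, as.data.frame(x)),
                        trace = FALSE, maxit = 500, MaxNWts = 100000)
  list(loglik = -fit$deviance / 2, converged = fit$convergence == 0, fit = fit)
}

#' Likelihood-ratio test for barcode information beyond depth
#'
#' Fits two multinomial logistic models on all data: labels ~ depth
#' (reduced) and labels ~ depth + barcode weights (full), and tests the
#' added weights with `LR = 2 (loglik_full - loglik_reduced)` against a
#' chi-square with `C x (K - 1)` degrees of freedom (C added features, K
#' classes).
#'
#' @param weights `n x C` barcode matrix.
#' @param depth Length-n numeric depth covariate.
#' @param labels Length-n class labels.
#' @return List with `lr`, `df`, `p_value`, `loglik_full`, `loglik_reduced`,
#'   `converged`.
#' @export
depth_lrt <- function(weights, depth, labels) {
  weights <- as.matrix(weights)
  stopifnot(length(depth) == nrow(weights), length(labels) == nrow(weights))
  K <- length(unique(labels))
  reduced <- multinom_loglik(matrix(depth, ncol = 1,
                                    dimnames = list(NULL, "depth")), labels)
  full <- multinom_loglik(cbind(depth = depth, weights), labels)
  lr <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- ncol(weights) * (K - 1)
  list(lr = lr, df = df, p_value = stats::pchisq(lr, df, lower.tail = FALSE),
       loglik_full = full$loglik, loglik_reduced = reduced$loglik,
       converged = full$converged && reduced$converged)
}

#' Expected balanced accuracy of uniform-random classification
#'
#' A classifier assigning labels uniformly at random has expected per-class
#' recall `1/K`, hence expected balanced accuracy `1/K` regardless of class
#' imbalance.
#'
#' @param n_classes Number of classes K.
#' @return `1 / n_classes`.
#' @export
chance_balanced_accuracy <- function(n_classes) 1 / n_classes

#' Synthetic barcode table with class structure
#'
#' Generates per-class feature templates (well separated or not, via
#' `separation`) plus isotropic noise, a depth covariate correlated with the
#' class label, and the bookkeeping columns used by the classification
#' pipeline. Used to exercise the barcode module without recorded data.
#'
#' @param n Number of neurons.
#' @param n_classes Number of classes.
#' @param n_features Barcode dimensionality.
#' @param separation Distance scale between class template means (0 =
#'   uninformative barcodes).
#' @param depth_effect Strength of the class-depth association.
#' @param noise Feature noise s.d.
#' @param seed RNG seed.
#' @return List with `x`, `labels`, `depth`, `templates`.
#' @export
synthetic_barcodes <- function(n = 400L, n_classes = 4L, n_features = 16L,
                               separation = 3, depth_effect = 1, noise = 1,
                               seed = 1L) {
  with_preserved_seed(seed, {
    templates <- matrix(stats::rnorm(n_classes * n_features), n_classes)
    templates <- templates / sqrt(rowSums(templates^2)) * separation
    labels <- sample(rep_len(seq_len(n_classes), n))
    x <- templates[labels, , drop = FALSE] +
      matrix(stats::rnorm(n * n_features, sd = noise), n)
    depth <- 100 * labels * depth_effect + stats::rnorm(n, sd = 50)
    list(x = x, labels = paste0("class", labels), depth = depth,
         templates = templates)
  })
}
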