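## ---- standard cross-validation baseline (V2) ------------------------------
##
## The conventional direction: each feature is scored by how well it predicts
## the observed classification in k-fold cross-validation (logistic model and
## held-out accuracy for binary labels, linear model and held-out MSE for
## semi-quantitative labels); the top n features are passed on to model
## building. Unlike the inverted-role screen this ranking always returns a
## candidate set, so a model is (almost) always fitted -- even when the labels
## carry no information about the data.

seeded_folds <- function(n, k_folds, seed) {
  if (k_folds < 2L || k_folds > n) stopf("k_folds must lie in [2, %d]", n)
  with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
}

#' Standard CV accuracy of one feature (binary labels)
#'
#' k-fold cross-validation of the logistic model `classification ~ feature`;
#' held-out predicted probabilities are thresholded at 0.5 and the fraction of
#' correct held-out predictions returned. A fold whose logistic fit does not
#' converge predicts the training-split majority class (with a warning);
#' under complete separation the held-out probabilities are finite and
#' bounded, so the accuracy is always well defined.
#'
#' @param feature Numeric vector (one feature across samples).
#' @param classification 0/1 vector; both classes must be present.
#' @param k_folds Number of folds (default 10, the classification-CV
#'   convention of the DAAG tools the baseline mirrors).
#' @param seed Seed for the fold assignment.
#' @return Held-out accuracy in `[0, 1]`.
#' @export
cv_standard_binary <- function(feature, classification, k_folds = 10L, seed = NULL) {
  if (!all(classification %in% c(0, 1))) stopf("invalid input: labels must be binary 0/1")
  if (length(unique(classification)) < 2L)
    stopf("invalid input: both classes must be present")
  n <- length(classification)
  folds <- seeded_folds(n, k_folds, seed)
  pred <- integer(n)
  for (f in seq_len(k_folds)) {
    test <- folds == f
    ytr <- classification[!test]
    xtr <- feature[!test]
    if (sd(xtr) == 0 || length(unique(ytr)) < 2L) {
      pred[test] <- as.integer(mean(ytr) >= 0.5)
      next
    }
    X <- cbind(1, xtr)
    fit <- glm_irls(X, as.numeric(ytr), binomial = TRUE)
    ## a zero-deviance fit is complete separation, not non-convergence: the
    ## held-out probabilities are finite (clamped), so the fit is usable
    if (!fit$converged && fit$deviance >= 1e-3) {
      warning(sprintf("fold %d: logistic fit did not converge; using majority class", f))
      pred[test] <- as.integer(mean(ytr) >= 0.5)
      next
    }
    eta <- cbind(1, feature[test]) %*% fit$coefficients
    prob <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    pred[test] <- as.integer(prob >= 0.5)
  }
  mean(pred == classification)
}

#' Standard CV error of one feature (semi-quantitative labels)
#'
#' k-fold cross-validation of the linear model `classification ~ feature`;
#' returns the mean squared error of the held-out predictions.
#'
#' @param feature Numeric vector.
#' @param classification Numeric (semi-quantitative) classification.
#' @param k_folds Number of folds (default 3).
#' @param seed Seed for the fold assignment.
#' @return Held-out mean squared error.
#' @export
cv_standard_linear <- function(feature, classification, k_folds = 3L, seed = NULL) {
  n <- length(classification)
  folds <- seeded_folds(n, k_folds, seed)
  sse <- 0
  for (f in seq_len(k_folds)) {
    test <- folds == f
    X <- cbind(1, feature[!test])
    cf <- qr.coef(qr(X), classification[!test])
    cf[is.na(cf)] <- 0
    pred <- cbind(1, feature[test]) %*% cf
    sse <- sse + sum((classification[test] - pred)^2)
  }
  sse / n
}

#' Top features by standard CV score
#'
#' @param scores Per-feature CV scores.
#' @param n Maximum number of features to keep (the number of samples in the
#'   reference design).
#' @param direction `"lower"` if smaller scores are better (CV error) or
#'   `"higher"` (CV accuracy).
#' @param feature_idx Original feature indices the scores belong to.
#' @return Ordered integer vector of at most `n` selected feature indices;
#'   ties are broken by original feature order.
#' @export
select_top_v2 <- function(scores, n, direction = c("lower", "higher"),
                          feature_idx = seq_along(scores)) {
  direction <- match.arg(direction)
  if (n < 1) stopf("n must be >= 1")
  key <- if (direction == "lower") scores else -scores
  ord <- order(key, feature_idx)
  feature_idx[ord][seq_len(min(length(scores), n))]
}

#' Standard cross-validation feature ranking (V2)
#'
#' Ranks every feature by univariate prediction of the classification
#' ([cv_standard_binary()] for `type = "lr"`, [cv_standard_linear()] for
#' `type = "lm"`) and keeps the top `n_select` features. All features share
#' one seeded fold assignment.
#'
#' @param features Numeric matrix, features in rows and samples in columns.
#' @param classification Observed classification.
#' @param type `"lr"` (binary, logistic, accuracy) or `"lm"` (linear, MSE).
#' @param k_folds Number of folds; defaults to 10 for `"lr"` and 3 for `"lm"`.
#' @param n_select Cap on the number of selected features; defaults to the
#'   number of samples.
#' @param seed Seed for the fold assignment.
#' @return An object of class `cv_ranking` with per-feature `score`, the
#'   score `direction` and the ordered `selected_idx`.
#' @export
baseline_rank <- function(features, classification, type = c("lr", "lm"),
                          k_folds = NULL, n_select = NULL, seed = NULL) {
  type <- match.arg(type)
  features <- as.matrix(features)
  if (is.null(k_folds)) k_folds <- if (type == "lr") 10L else 3L
  if (is.null(n_select)) n_select <- ncol(features)
  score <- vapply(seq_len(nrow(features)), function(j) {
    if (type == "lr")
      cv_standard_binary(features[j, ], classification, k_folds, seed)
    else
      cv_standard_linear(features[j, ], classification, k_folds, seed)
  }, numeric(1))
  direction <- if (type == "lr") "higher" else "lower"
  structure(list(score = score, direction = direction,
                 selected_idx = select_top_v2(score, n_select, direction),
                 type = type, feature_ids = rownames(features)),
            class = "cv_ranking")
}

#' @export
print.cv_ranking <- function(x, ...) {
  cat(sprintf("cv_ranking (%s, %s-is-better): %d features, %d selected\n",
              x$type, if (x$direction == "lower") "lower" else "higher",
              length(x$score), length(x$selected_idx)))
  invisible(x)
}
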