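## ---- inverted-role pre-filtering (V1) -------------------------------------
##
## The screen deliberately reverses the usual modelling direction: each
## feature is the DEPENDENT variable and the (error-prone) classification the
## predictor. Features that respond to the observed classification are tested
## by a linear-model likelihood-ratio test, the p-values are adjusted for
## multiplicity, and the surviving features are ranked by cross-validation
## error, still in inverted roles.

## Multi-response least-squares residual sums of squares.
## Y: samples x features; Z: design matrix. Returns per-feature RSS.
rss_multi <- function(Z, Y) {
  qz <- qr(Z)
  res <- qr.resid(qz, Y)
  colSums(res^2)
}

## Vectorised per-feature LRT screen; the single-feature wrapper and the
## high-level prefilter() both funnel through this.
lrt_screen_matrix <- function(features, classification, covariates = NULL) {
  n <- ncol(features)
  if (length(classification) != n)
    stopf("classification length (%d) does not match number of samples (%d)",
          length(classification), n)
  if (length(unique(classification)) < 2L)
    stopf("degenerate design: classification is constant")
  Z0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  Z1 <- cbind(Z0, classification = as.numeric(classification))
  Y <- t(features)
  rss0 <- rss_multi(Z0, Y)
  rss1 <- rss_multi(Z1, Y)
  df <- ncol(Z1) - ncol(Z0)
  p <- rep(1, nrow(features))
  eps0 <- 1e-12 * n
  degenerate <- rss0 > eps0 & rss1 <= rss0 * 1e-12
  regular <- rss0 > eps0 & !degenerate
  lrt <- n * log(rss0[regular] / rss1[regular])
  p[regular] <- pchisq(lrt, df = df, lower.tail = FALSE)
  p[degenerate] <- 0
  attr(p, "degenerate") <- which(degenerate)
  p
}

#' Linear-model likelihood-ratio p-value for one feature
#'
#' Fits `feature ~ classification (+ covariates)` against the null model
#' `feature ~ 1 (+ covariates)` by least squares and returns the chi-square
#' tail probability of the likelihood-ratio statistic
#' `n * log(RSS_null / RSS_full)` with one degree of freedom per added term.
#' The classification enters as a single numeric regressor (binary 0/1 and
#' semi-quantitative ratings alike, assuming equidistant categories).
#' Covariates, when given, are part of BOTH models, so the test isolates the
#' classification term.
#'
#' A feature with (covariate-adjusted) zero variance yields p = 1 (never
#' selected); a feature fitted exactly by the full model yields p = 0 with a
#' `"degenerate"` attribute.
#'
#' @param feature Numeric vector (one feature across samples).
#' @param classification Numeric vector, the observed classification; must not
#'   be constant.
#' @param covariates Optional numeric matrix of additional covariates
#'   (samples in rows).
#' @return P-value in `[0, 1]`.
#' @export
lrt_pvalue <- function(feature, classification, covariates = NULL) {
  p <- lrt_screen_matrix(matrix(feature, nrow = 1), classification, covariates)
  out <- p[1]
  attr(out, "degenerate") <- length(attr(p, "degenerate")) > 0
  out
}

#' Adjust p-values for multiplicity
#'
#' Thin validation wrapper around [stats::p.adjust()] restricted to the
#' adjustment schemes used by the pre-filter.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method One of `"BH"`, `"bonferroni"`, `"holm"`, `"none"`.
#' @return Adjusted p-values, capped at 1, in input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "holm", "none")) {
  if (length(method) != 1L || !method %in% c("BH", "bonferroni", "holm", "none"))
    stopf("unknown p-value adjustment method: %s",
          paste(as.character(method), collapse = ", "))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Significant features at an adjusted-p cutoff
#'
#' @param adjusted_p Vector of adjusted p-values.
#' @param alpha Significance threshold; features with `adjusted_p < alpha`
#'   (strictly below) are retained.
#' @return Integer vector of significant feature indices.
#' @export
filter_significant <- function(adjusted_p, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  which(adjusted_p < alpha)
}

## Shared k-fold CV machinery on inverted roles: regress each feature on the
## classification, predict held-out feature values, return per-feature MSE.
cv_inverted_matrix <- function(features, classification, covariates = NULL,
                               k_folds = 3L, seed = NULL) {
  n <- ncol(features)
  if (k_folds < 2L || k_folds > n)
    stopf("k_folds must lie in [2, %d]", n)
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  Z <- cbind(`(Intercept)` = rep(1, n), covariates,
             classification = as.numeric(classification))
  Y <- t(features)
  sse <- rep(0, nrow(features))
  n_pred <- 0L
  for (f in seq_len(k_folds)) {
    test <- folds == f
    if (length(unique(classification[!test])) < 2L) {
      warning(sprintf("fold %d skipped: constant classification in training split", f))
      next
    }
    B <- qr.coef(qr(Z[!test, , drop = FALSE]), Y[!test, , drop = FALSE])
    B[is.na(B)] <- 0
    pred <- Z[test, , drop = FALSE] %*% B
    sse <- sse + colSums((Y[test, , drop = FALSE] - pred)^2)
    n_pred <- n_pred + sum(test)
  }
  if (n_pred == 0L) stopf("undefined CV: all folds skipped")
  sse / n_pred
}

#' Inverted-role cross-validation error of one feature
#'
#' k-fold cross-validation of the linear model `feature ~ classification
#' (+ covariates)`, i.e. still with roles reversed: the feature is predicted
#' from the classification and the mean squared error of the held-out
#' predictions is returned. Fold assignment is seeded; folds whose training
#' split has a constant classification are skipped with a warning.
#'
#' @inheritParams lrt_pvalue
#' @param k_folds Number of folds (default 3, the linear-model CV convention
#'   of the DAAG tools the screen mirrors).
#' @param seed Seed for the fold assignment.
#' @return Mean squared prediction error (non-negative).
#' @export
cv_inverted <- function(feature, classification, covariates = NULL,
                        k_folds = 3L, seed = NULL) {
  cv_inverted_matrix(matrix(feature, nrow = 1), classification, covariates,
                     k_folds, seed)[1]
}

#' Top features by inverted-role CV error
#'
#' Orders the significant features by ascending cross-validation error and
#' truncates to `min(length(cv_errors), n_samples)` (the number of retained
#' features never exceeds the number of samples). Ties are broken by original
#' feature order, keeping runs reproducible.
#'
#' @param cv_errors CV errors of the significant features.
#' @param n_samples Number of samples (the cap).
#' @param feature_idx Original feature indices the errors belong to.
#' @return Ordered integer vector of selected feature indices.
#' @export
select_top_v1 <- function(cv_errors, n_samples, feature_idx = seq_along(cv_errors)) {
  if (length(cv_errors) == 0L) return(integer(0))
  stopifnot(length(cv_errors) == length(feature_idx))
  ord <- order(cv_errors, feature_idx)
  feature_idx[ord][seq_len(min(length(cv_errors), n_samples))]
}

#' Inverted-role feature pre-filter (V1)
#'
#' The full pre-filtering heuristic: per-feature likelihood-ratio screen with
#' the classification as predictor, multiplicity adjustment, significance cut
#' at `alpha`, inverted-role cross-validation of the surviving features, and
#' truncation to at most `n_samples` features with the lowest CV errors.
#'
#' @param features Numeric matrix, features in rows and samples in columns.
#' @param classification Observed (possibly error-prone) classification.
#' @param covariates Optional numeric covariate matrix (samples in rows),
#'   included in both the null and full screening models and in the CV step.
#' @param adjust Multiplicity adjustment, see [adjust_pvalues()].
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param k_folds CV folds (default 3).
#' @param seed Seed for the CV fold assignment.
#' @return An object of class `prefilter_result` with per-feature `raw_p`,
#'   `adjusted_p`, `cv_error` (NA for non-significant features),
#'   `significant_idx` and the ordered `selected_idx`. An empty
#'   `selected_idx` signals the downstream no-model condition.
#' @export
prefilter <- function(features, classification, covariates = NULL,
                      adjust = "BH", alpha = 0.05, k_folds = 3L, seed = NULL) {
  features <- as.matrix(features)
  raw_p <- lrt_screen_matrix(features, classification, covariates)
  adjusted_p <- adjust_pvalues(as.numeric(raw_p), adjust)
  significant_idx <- filter_significant(adjusted_p, alpha)
  cv_error <- rep(NA_real_, nrow(features))
  selected_idx <- integer(0)
  if (length(significant_idx)) {
    cv_error[significant_idx] <- cv_inverted_matrix(
      features[significant_idx, , drop = FALSE], classification, covariates,
      k_folds, seed)
    selected_idx <- select_top_v1(cv_error[significant_idx], ncol(features),
                                  significant_idx)
  }
  structure(list(raw_p = as.numeric(raw_p), adjusted_p = adjusted_p,
                 significant_idx = significant_idx, cv_error = cv_error,
                 selected_idx = selected_idx, alpha = alpha, adjust = adjust,
                 feature_ids = rownames(features)),
            class = "prefilter_result")
}

#' @export
print.prefilter_result <- function(x, ...) {
  cat(sprintf("prefilter_result (%s, alpha = %g): %d/%d significant, %d selected\n",
              x$adjust, x$alpha, length(x$significant_idx), length(x$raw_p),
              length(x$selected_idx)))
  invisible(x)
}

#' @export
as.data.frame.prefilter_result <- function(x, ...) {
  rank <- rep(NA_integer_, length(x$raw_p))
  rank[x$selected_idx] <- seq_along(x$selected_idx)
  data.frame(feature_id = if (!is.null(x$feature_ids)) x$feature_ids
             else paste0("feat", seq_along(x$raw_p)),
             raw_p = x$raw_p, adjusted_p = x$adjusted_p,
             significant = seq_along(x$raw_p) %in% x$significant_idx,
             cv_error = x$cv_error, rank = rank)
}
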