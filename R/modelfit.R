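## ---- final model training -------------------------------------------------
##
## After pre-filtering the roles return to normal: the classification is the
## dependent variable, modelled from the selected features by a logistic
## regression (binary) or a linear model (semi-quantitative), and reduced by
## backward stepwise deletion under AIC (default), BIC or cross-validation
## error. Gaussian fits use QR least squares; logistic fits use the package's
## IRLS routine (C++), since the benchmark refits thousands of models.

## Floor for residual sums of squares so the profile Gaussian log-likelihood
## stays finite for saturated fits; such fits are flagged degenerate.
rss_floor <- function(y) max(1e-10, 1e-12 * sum(y^2))

refit_engine <- function(M, y, family, maxit = 25L, tol = 1e-8, start = NULL) {
  n <- length(y)
  if (family == "gaussian") {
    cf <- qr.coef(qr(M), y)
    cf[is.na(cf)] <- 0
    rss <- sum((y - M %*% cf)^2)
    degenerate <- rss < rss_floor(y)
    ll <- -n / 2 * (log(2 * pi) + log(max(rss, rss_floor(y)) / n) + 1)
    list(coefficients = as.numeric(cf), deviance = rss, log_likelihood = ll,
         converged = TRUE, degenerate = degenerate)
  } else {
    fit <- glm_irls(M, as.numeric(y), binomial = TRUE, maxit = maxit, tol = tol,
                    dev_min = 1e-5, start = start)
    eta <- M %*% fit$coefficients
    list(coefficients = as.numeric(fit$coefficients), deviance = fit$deviance,
         log_likelihood = -fit$deviance / 2, converged = fit$converged,
         degenerate = fit$deviance < 1e-3, boundary = any(abs(eta) > 28))
  }
}

new_fitted_model <- function(fit, M, y, family, terms) {
  structure(list(family = family, terms = terms,
                 coefficients = stats::setNames(fit$coefficients, colnames(M)),
                 log_likelihood = fit$log_likelihood, deviance = fit$deviance,
                 converged = fit$converged, degenerate = isTRUE(fit$degenerate),
                 boundary = isTRUE(fit$boundary), n = length(y),
                 criterion_kind = NA_character_, criterion_value = NA_real_,
                 design = M, y = y),
            class = "fitted_model")
}

#' Fit a (generalized) linear model on selected features
#'
#' Maximum-likelihood fit of `y ~ X` with an intercept: iteratively reweighted
#' least squares for the logistic family, QR least squares for the gaussian
#' family. Rank-deficient designs are handled by dropping aliased columns
#' (with a warning), so a fit is returned even when the number of candidate
#' features reaches the number of samples; such saturated fits are flagged
#' `degenerate`. A logistic fit that does not converge within the iteration
#' cap is flagged `converged = FALSE`; unless it is a degenerate
#' (zero-deviance, complete-separation) fit it counts as a failed fit
#' downstream.
#'
#' @param X Numeric matrix of selected features, samples in rows and one
#'   column per feature (may have zero columns for an intercept-only model).
#' @param y Classification vector: 0/1 for `"logistic"`, numeric for
#'   `"gaussian"`.
#' @param family `"logistic"` or `"gaussian"`.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance
#'   (the usual GLM convergence convention).
#' @return An object of class `fitted_model` carrying the retained `terms`,
#'   `coefficients` (including the intercept), `log_likelihood`, `deviance`,
#'   and convergence/degeneracy flags.
#' @export
fit_glm <- function(X, y, family = c("logistic", "gaussian"),
                    maxit = 25L, tol = 1e-8) {
  family <- match.arg(family)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stopf("X and y dimensions do not match")
  if (family == "logistic") {
    if (!all(y %in% c(0, 1))) stopf("logistic family requires 0/1 outcome")
    if (length(unique(y)) < 2L) stopf("degenerate outcome: only one class present")
  }
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  M <- cbind(`(Intercept)` = rep(1, length(y)), X)
  qm <- qr(M)
  if (qm$rank < ncol(M)) {
    keep <- qm$pivot[seq_len(qm$rank)]
    warning(sprintf("design is rank deficient; dropping %d aliased column(s)",
                    ncol(M) - qm$rank))
    M <- M[, sort(keep), drop = FALSE]
  }
  fit <- refit_engine(M, y, family, maxit = maxit, tol = tol)
  new_fitted_model(fit, M, y, family, setdiff(colnames(M), "(Intercept)"))
}

#' Information criterion of a fitted model
#'
#' `AIC = -2 * logLik + 2 * k` and `BIC = -2 * logLik + log(n) * k`, where `k`
#' counts all estimated parameters (coefficients, plus the residual variance
#' for the gaussian family, whose log-likelihood is the profile Gaussian
#' form). With these conventions the values coincide with the standard
#' stepwise-selection criteria up to column-identical constants, so criterion
#' differences between nested candidates match the reference behaviour.
#'
#' @param model A `fitted_model`.
#' @param kind `"AIC"` or `"BIC"`.
#' @param n Number of samples (defaults to the model's).
#' @return Criterion value (smaller is better).
#' @export
information_criterion <- function(model, kind = c("AIC", "BIC"), n = model$n) {
  kind <- match.arg(kind)
  k <- length(model$coefficients) + (model$family == "gaussian")
  penalty <- if (kind == "AIC") 2 else log(n)
  -2 * model$log_likelihood + penalty * k
}

## k-fold CV error of a design: misclassification rate (logistic) or MSE
## (gaussian). Folds are supplied by the caller so candidate deletions within
## one stepwise round are compared on identical splits.
cv_error_design <- function(M, y, family, folds) {
  n <- length(y)
  err <- 0
  for (f in unique(folds)) {
    test <- folds == f
    fit <- refit_engine(M[!test, , drop = FALSE], y[!test], family)
    pred <- M[test, , drop = FALSE] %*% fit$coefficients
    if (family == "logistic") {
      err <- err + sum((plogis(pred) >= 0.5) != (y[test] == 1))
    } else {
      err <- err + sum((y[test] - pred)^2)
    }
  }
  err / n
}

#' Backward stepwise model reduction
#'
#' Starting from a fitted full model, repeatedly evaluates the criterion for
#' every single-term deletion and removes the term yielding the lowest
#' criterion, as long as that strictly improves on the current model; the
#' intercept is never removed. Criteria: `"AIC"` (default), `"BIC"`, or
#' `"CV"` (k-fold cross-validation error -- misclassification rate for the
#' logistic family, MSE for the gaussian family -- with one seeded fold
#' assignment per round, so candidate deletions are compared on identical
#' splits).
#'
#' @param model A converged `fitted_model` from [fit_glm()].
#' @param criterion `"AIC"`, `"BIC"` or `"CV"`.
#' @param k_folds Folds for the CV criterion.
#' @param seed Seed for the CV criterion's fold assignments.
#' @return The reduced `fitted_model` with `criterion_kind` and
#'   `criterion_value` filled in; if every candidate refit fails the last
#'   valid model is returned with a warning.
#' @export
stepwise_backward <- function(model, criterion = c("AIC", "BIC", "CV"),
                              k_folds = 5L, seed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(model, "fitted_model"))
  M <- model$design
  y <- model$y
  family <- model$family
  n <- length(y)

  crit_of <- function(fit, ncoef, folds, Msub) {
    if (criterion == "CV") return(cv_error_design(Msub, y, family, folds))
    k <- ncoef + (family == "gaussian")
    penalty <- if (criterion == "AIC") 2 else log(n)
    -2 * fit$log_likelihood + penalty * k
  }

  current <- refit_engine(M, y, family)
  round_i <- 0L
  folds <- if (criterion == "CV")
    seeded_folds(n, min(k_folds, n), derive_seed(seed, round_i)) else NULL
  current_crit <- crit_of(current, ncol(M), folds, M)

  repeat {
    terms <- setdiff(colnames(M), "(Intercept)")
    if (!length(terms)) break
    ## no deletion can beat a zero-deviance candidate: its criterion equals
    ## the analytic lower bound, so the scan can stop there (ties among
    ## perfect-fit candidates are thereby broken by term order)
    k_sub <- ncol(M) - 1L + (family == "gaussian")
    penalty <- if (criterion == "BIC") log(n) else 2
    bound <- if (criterion == "CV") -Inf
             else if (family == "gaussian")
               n * (log(rss_floor(y) / n) + 1 + log(2 * pi)) + penalty * k_sub
             else penalty * k_sub
    cand_crit <- rep(NA_real_, length(terms))
    cand_fits <- vector("list", length(terms))
    cur_coef <- stats::setNames(current$coefficients, colnames(M))
    for (i in seq_along(terms)) {
      Msub <- M[, colnames(M) != terms[i], drop = FALSE]
      ## warm-start each deletion from the current coefficients: the MLE is
      ## unchanged, only the iteration count drops
      fit <- refit_engine(Msub, y, family,
                          start = unname(cur_coef[colnames(Msub)]))
      ## finite likelihood suffices for criterion comparison (step semantics);
      ## convergence of the FINAL model is what decides a successful fit
      if (!is.finite(fit$log_likelihood)) next
      cand_fits[[i]] <- fit
      cand_crit[i] <- crit_of(fit, ncol(Msub), folds, Msub)
      if (cand_crit[i] <= bound + 1e-8) break
    }
    if (all(is.na(cand_crit))) {
      warning("all candidate refits failed; returning last valid model")
      break
    }
    best <- which.min(cand_crit)
    if (!(cand_crit[best] < current_crit)) break
    M <- M[, colnames(M) != terms[best], drop = FALSE]
    current <- cand_fits[[best]]
    current_crit <- cand_crit[best]
    round_i <- round_i + 1L
    if (criterion == "CV") {
      folds <- seeded_folds(n, min(k_folds, n), derive_seed(seed, round_i))
      current_crit <- crit_of(current, ncol(M), folds, M)
    }
  }

  out <- new_fitted_model(current, M, y, family, setdiff(colnames(M), "(Intercept)"))
  out$criterion_kind <- criterion
  out$criterion_value <- current_crit
  out
}

#' Per-sample scores of a fitted model
#'
#' @param model A `fitted_model`.
#' @param X New data, samples in rows, containing a column for every model
#'   term (extra columns are ignored).
#' @return Numeric score vector: predicted probabilities in `(0, 1)` for the
#'   logistic family, fitted values for the gaussian family.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "fitted_model"))
  X <- as.matrix(X)
  missing <- setdiff(model$terms, colnames(X))
  if (length(missing))
    stopf("schema error: model terms missing from new data: %s",
          paste(missing, collapse = ", "))
  M <- cbind(`(Intercept)` = rep(1, nrow(X)),
             X[, model$terms, drop = FALSE])
  eta <- as.numeric(M %*% model$coefficients[colnames(M)])
  if (model$family == "logistic") pmin(pmax(plogis(eta), 1e-15), 1 - 1e-15) else eta
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("fitted_model (%s): %d term(s) + intercept, logLik = %.3f%s\n",
              x$family, length(x$terms), x$log_likelihood,
              if (!x$converged) " [NOT converged]" else ""))
  if (!is.na(x$criterion_kind))
    cat(sprintf("  %s = %.3f after backward selection\n",
                x$criterion_kind, x$criterion_value))
  invisible(x)
}

## Serialise a fitted model to JSON (terms + coefficients are what a user
## needs to apply the model elsewhere).
#' Write / read a fitted model as JSON
#'
#' @param model A `fitted_model`.
#' @param path JSON file path.
#' @return `write_model()` the path invisibly; `read_model()` a list with the
#'   model family, terms and coefficients plus fit diagnostics (sufficient
#'   for [predict_scores()]).
#' @export
write_model <- function(model, path) {
  obj <- list(family = model$family, terms = model$terms,
              coefficients = as.list(model$coefficients),
              log_likelihood = model$log_likelihood, deviance = model$deviance,
              criterion_kind = model$criterion_kind,
              criterion_value = model$criterion_value,
              converged = model$converged, n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$terms <- as.character(obj$terms)
  class(obj) <- "fitted_model"
  obj
}
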