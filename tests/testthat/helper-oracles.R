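## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths: AUC by pair counting, LOO-CV by
## refitting n times, stepwise selection by greedy enumeration on stats fits.

## AUC by exhaustive pair counting, ties scored 1/2; fixed orientation.
bf_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

## Multiclass AUC as the plain average of pairwise fixed-orientation AUCs,
## the higher class label acting as the positive class.
bf_auc_multiclass <- function(scores, truth) {
  cl <- sort(unique(truth))
  pairs <- combn(cl, 2)
  mean(apply(pairs, 2, function(p) {
    keep <- truth %in% p
    bf_auc(scores[keep], as.integer(truth[keep] == p[2]))
  }))
}

## Leave-one-out CV of lm(y ~ x) by explicit refitting; returns MSE.
bf_loo_mse <- function(x, y) {
  n <- length(y)
  se <- numeric(n)
  for (i in seq_len(n)) {
    fit <- lm(y[-i] ~ x[-i])
    se[i] <- (y[i] - coef(fit)[1] - coef(fit)[2] * x[i])^2
  }
  mean(se)
}

## Greedy backward selection oracle: at every round refit every single-term
## deletion with stats::glm/lm, compare stats::AIC / BIC, delete the best
## strictly improving candidate. Returns the retained term names.
bf_greedy_backward <- function(X, y, family, kind = "AIC") {
  terms <- colnames(X)
  crit <- function(tms) {
    f <- if (length(tms))
      as.formula(paste("y ~", paste(sprintf("`%s`", tms), collapse = "+")))
    else y ~ 1
    dat <- data.frame(y = y, X, check.names = FALSE)
    fit <- if (family == "logistic")
      suppressWarnings(glm(f, data = dat, family = binomial))
    else lm(f, data = dat)
    if (kind == "AIC") AIC(fit) else BIC(fit)
  }
  cur <- crit(terms)
  repeat {
    if (!length(terms)) break
    cand <- vapply(seq_along(terms), function(i) crit(terms[-i]), numeric(1))
    best <- which.min(cand)
    if (!(cand[best] < cur)) break
    cur <- cand[best]
    terms <- terms[-best]
  }
  terms
}

## Small reproducible two-group feature matrix for pipeline-level tests.
make_toy_dataset <- function(seed = 1, n_per_group = 15, n_features = 40,
                             n_informative = 5, delta = 3, sd = 1) {
  cfg <- sim_config(n_samples = 2 * n_per_group, n_features = n_features,
                    n_groups = 2, frac_informative = 0, mean_diff = delta,
                    sd = sd, prob1 = 0, prob2 = 1, encoding = "binary",
                    seed = seed)
  ds <- simulate_dataset(cfg)
  ## force a known informative set for deterministic recovery checks
  idx <- seq_len(n_informative)
  ds$features[idx, ] <- ds$features[idx, ] +
    rep(ds$true_labels * delta, each = n_informative)
  ds$informative_idx <- idx
  ds
}
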