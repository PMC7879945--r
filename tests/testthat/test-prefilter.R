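test_that("LRT p-value matches a stats-based Gaussian likelihood-ratio oracle", {
  set.seed(42)
  x <- rnorm(10)
  cls <- rep(c(0, 1), 5)
  p <- lrt_pvalue(x, cls)
  full <- lm(x ~ cls)
  null <- lm(x ~ 1)
  lrt <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null)))
  expect_equal(as.numeric(p), pchisq(lrt, df = 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("LRT degeneracies are handled: exact fit, constant feature, constant labels", {
  cls <- rep(c(0, 1), 10)
  p <- lrt_pvalue(2 * cls, cls)            # noiseless linear relation
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))
  expect_equal(as.numeric(lrt_pvalue(rep(3, 20), cls)), 1)  # zero variance
  expect_error(lrt_pvalue(rnorm(20), rep(1, 20)), "degenerate design")
})

test_that("LRT p-values are uniform under the null", {
  set.seed(7)
  cls <- rep(c(0, 1), each = 25)
  feats <- matrix(rnorm(1500 * 50), nrow = 1500)
  p <- invsel:::lrt_screen_matrix(feats, cls)
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("covariates are partialled out of the screen", {
  set.seed(8)
  n <- 60
  cls <- rep(c(0, 1), each = n / 2)
  z <- rnorm(n)
  ## feature driven by the covariate only: no classification signal
  p_only_cov <- vapply(1:200, function(i)
    as.numeric(lrt_pvalue(2 * z + rnorm(n), cls, covariates = cbind(z))), numeric(1))
  expect_gt(ks.test(p_only_cov, "punif")$p.value, 0.01)
  ## feature driven by the classification: detected despite the covariate
  p_sig <- as.numeric(lrt_pvalue(2 * cls + z + rnorm(n, sd = 0.5), cls,
                                 covariates = cbind(z)))
  expect_lt(p_sig, 1e-6)
})

test_that("p-value adjustment wraps the standard schemes and validates input", {
  expect_equal(adjust_pvalues(c(0.01, 0.02), "bonferroni"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  p <- runif(10)
  expect_identical(adjust_pvalues(p, "none"), p)
  expect_true(all(adjust_pvalues(p, "holm") >= p))
  expect_error(adjust_pvalues(p, "fdr2"), "unknown")
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "0, 1")
})

test_that("significance cut is strictly below alpha", {
  expect_identical(filter_significant(c(0.04, 0.05, 0.06), 0.05), 1L)
  expect_identical(filter_significant(rep(1, 5)), integer(0))
  expect_identical(filter_significant(rep(0, 3)), 1:3)
})

test_that("inverted-role LOO CV matches brute-force refitting", {
  set.seed(3)
  x <- rnorm(6)
  cls <- c(0, 1, 0, 1, 1, 0)
  got <- cv_inverted(x, cls, k_folds = 6, seed = 1)
  ## LOO: fold contents do not depend on the shuffle, only the partition does
  expect_equal(got, bf_loo_mse(cls, x), tolerance = 1e-10)
})

test_that("inverted-role CV separates signal from noise and is ~0 when noiseless", {
  cls <- rep(c(0, 1), each = 20)
  expect_lt(cv_inverted(2 * cls, cls, k_folds = 5, seed = 1), 1e-20)
  wins <- vapply(1:40, function(s) {
    set.seed(s)
    noise <- rnorm(40)                       # sd 1, no class signal
    signal <- 2 * cls + rnorm(40, sd = 0.5)  # class signal, smaller residual
    cv_inverted(signal, cls, k_folds = 3, seed = s) <
      cv_inverted(noise, cls, k_folds = 3, seed = s)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("V1 top selection orders by CV error, caps at n, breaks ties by index", {
  expect_identical(select_top_v1(c(0.5, 0.1, 0.3), 50), c(2L, 3L, 1L))
  expect_identical(select_top_v1(runif(80), 50) |> length(), 50L)
  expect_identical(select_top_v1(rep(0.2, 4), 50, feature_idx = c(9L, 3L, 5L, 1L)),
                   c(1L, 3L, 5L, 9L))
  expect_identical(select_top_v1(numeric(0), 10), integer(0))
})

test_that("prefilter recovers informative features and shrinks with alpha", {
  ds <- make_toy_dataset(seed = 2, delta = 3)
  pf <- prefilter(ds$features, ds$observed_labels, adjust = "BH", seed = 1)
  expect_true(all(ds$informative_idx %in% pf$selected_idx))
  expect_true(all(pf$selected_idx %in% pf$significant_idx))
  expect_true(all(pf$adjusted_p >= pf$raw_p))
  pf_strict <- prefilter(ds$features, ds$observed_labels, adjust = "BH",
                         alpha = 0.001, seed = 1)
  expect_true(all(pf_strict$significant_idx %in% pf$significant_idx))
  ## output table shape
  tab <- as.data.frame(pf)
  expect_named(tab, c("feature_id", "raw_p", "adjusted_p", "significant",
                      "cv_error", "rank"))
  expect_identical(sum(!is.na(tab$rank)), length(pf$selected_idx))
})

test_that("family-wise error of the Bonferroni screen is near alpha under the null", {
  hits <- vapply(1:400, function(s) {
    set.seed(s)
    feats <- matrix(rnorm(50 * 30), nrow = 50)
    cls <- rep(c(0, 1), each = 15)
    p <- invsel:::lrt_screen_matrix(feats, cls)
    any(adjust_pvalues(as.numeric(p), "bonferroni") < 0.05)
  }, logical(1))
  ## chi-square LRT at n = 30 is mildly anticonservative; allow for that
  expect_lt(mean(hits), 0.12)
  expect_gt(mean(hits), 0.005)
})
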