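test_that("logistic and gaussian fits match closed forms and the stats oracle", {
  ## intercept-only logistic: logit of the mean
  y <- rep(c(1, 0), c(10, 30))
  m0 <- fit_glm(NULL, y, "logistic")
  expect_equal(unname(m0$coefficients[1]), qlogis(0.25), tolerance = 1e-6)
  ## noiseless gaussian: exact coefficients, zero residual SS
  x <- seq(-2, 2, length.out = 20)
  mg <- fit_glm(cbind(x = x), 1 + 2 * x, "gaussian")
  expect_equal(unname(mg$coefficients), c(1, 2), tolerance = 1e-10)
  expect_lt(mg$deviance, 1e-20)
  ## 8-sample logistic fixture vs stats::glm
  set.seed(12)
  X8 <- cbind(a = rnorm(8))
  y8 <- c(0, 1, 0, 0, 1, 1, 0, 1)
  mine <- fit_glm(X8, y8, "logistic", tol = 1e-13)
  ref <- glm(y8 ~ X8, family = binomial, control = glm.control(epsilon = 1e-13))
  expect_equal(unname(mine$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(mine$deviance, ref$deviance, tolerance = 1e-8)
})

test_that("information criteria match stats::AIC / BIC and their identity", {
  set.seed(13)
  X <- cbind(a = rnorm(10), b = rnorm(10))
  y <- rnorm(10)
  m <- fit_glm(X, y, "gaussian")
  ref <- lm(y ~ X)
  expect_equal(information_criterion(m, "AIC"), AIC(ref), tolerance = 1e-8)
  expect_equal(information_criterion(m, "BIC"), BIC(ref), tolerance = 1e-8)
  k <- length(m$coefficients) + 1   # + residual variance
  expect_equal(information_criterion(m, "BIC") - information_criterion(m, "AIC"),
               (log(10) - 2) * k, tolerance = 1e-10)
  yb <- rep(c(0, 1), 5)
  mb <- fit_glm(X, yb, "logistic", tol = 1e-12)
  refb <- glm(yb ~ X, family = binomial)
  expect_equal(information_criterion(mb, "AIC"), AIC(refb), tolerance = 1e-6)
})

test_that("backward stepwise removes noise, keeps signal, and has a fixed point", {
  set.seed(15)
  n <- 40
  strong <- rnorm(n)
  noise <- rnorm(n)
  y <- as.integer(plogis(3 * strong) > runif(n))
  m <- fit_glm(cbind(strong = strong, noise = noise), y, "logistic")
  red <- stepwise_backward(m, "AIC")
  expect_identical(red$terms, "strong")
  ## fixed point: reducing again changes nothing
  red2 <- stepwise_backward(red, "AIC")
  expect_identical(red2$terms, red$terms)
  expect_lte(red$criterion_value, information_criterion(m, "AIC") + 1e-8)
})

test_that("stepwise agrees with the exhaustive greedy oracle on small designs", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 35
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    eta <- 1.5 * X[, 1] - 1.2 * X[, 3]
    yb <- as.integer(plogis(eta) > runif(n))
    if (length(unique(yb)) < 2) next
    mine <- stepwise_backward(fit_glm(X, yb, "logistic", tol = 1e-12), "AIC")
    expect_identical(sort(mine$terms), sort(bf_greedy_backward(X, yb, "logistic")),
                     label = sprintf("logistic AIC seed %d", seed))
    yg <- eta + rnorm(n)
    mine_g <- stepwise_backward(fit_glm(X, yg, "gaussian"), "BIC")
    expect_identical(sort(mine_g$terms),
                     sort(bf_greedy_backward(X, yg, "gaussian", "BIC")),
                     label = sprintf("gaussian BIC seed %d", seed))
  }
})

test_that("stepwise agrees with stats::step backward selection", {
  set.seed(15)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- X[, 2] - X[, 5] + rnorm(n)
  dat <- data.frame(y = y, X)
  ref <- step(lm(y ~ ., data = dat), direction = "backward", trace = 0)
  mine <- stepwise_backward(fit_glm(X, y, "gaussian"), "AIC")
  expect_setequal(mine$terms, setdiff(names(coef(ref)), "(Intercept)"))
})

test_that("the CV stepwise criterion is usable and seeded", {
  set.seed(16)
  n <- 40
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(plogis(2 * X[, 1]) > runif(n))
  a <- stepwise_backward(fit_glm(X, y, "logistic"), "CV", k_folds = 5, seed = 3)
  b <- stepwise_backward(fit_glm(X, y, "logistic"), "CV", k_folds = 5, seed = 3)
  expect_identical(a$terms, b$terms)
  expect_true("f1" %in% a$terms)
})

test_that("predicted scores are consistent with in-sample fitted values", {
  set.seed(17)
  X <- cbind(a = rnorm(25), b = rnorm(25))
  y <- rep(c(0, 1), c(12, 13))
  m <- fit_glm(X, y, "logistic")
  sc <- predict_scores(m, X)
  eta <- cbind(1, X) %*% m$coefficients
  expect_equal(sc, as.numeric(plogis(eta)), tolerance = 1e-12)
  expect_true(all(sc > 0 & sc < 1))
  ## gaussian closed form
  mg <- fit_glm(cbind(x = c(0, 1, 2)), c(1, 3, 5), "gaussian")
  expect_equal(predict_scores(mg, cbind(x = 3)), 7, tolerance = 1e-10)
  expect_error(predict_scores(m, cbind(a = 1)), "schema")
})

test_that("rank-deficient designs drop aliased columns instead of failing", {
  set.seed(18)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x, c = rnorm(20))
  y <- rep(c(0, 1), 10)
  expect_warning(m <- fit_glm(X, y, "logistic"), "rank deficient")
  expect_length(m$terms, 2L)
})

test_that("models round-trip through JSON and still predict", {
  set.seed(19)
  X <- cbind(a = rnorm(15), b = rnorm(15))
  y <- X[, 1] + rnorm(15)
  m <- stepwise_backward(fit_glm(X, y, "gaussian"), "AIC")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(predict_scores(back, X), predict_scores(m, X), tolerance = 1e-10)
})
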