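test_that("balanced group sizes split evenly with the remainder in the top group", {
  expect_identical(balanced_group_sizes(50, 2), c(25L, 25L))
  expect_identical(balanced_group_sizes(50, 3), c(16L, 16L, 18L))
  expect_identical(balanced_group_sizes(10, 10), rep(1L, 10))
  for (n in c(17, 50, 101)) for (k in c(2, 3, 7)) {
    s <- balanced_group_sizes(n, k)
    expect_identical(sum(s), as.integer(n))
    expect_true(all(s[-k] == n %/% k))
    expect_lte(s[k] - s[1], k - 1)
  }
  expect_error(balanced_group_sizes(3, 5), "invalid")
})

test_that("informative mask is Bernoulli per feature with the right mean", {
  expect_identical(sample_informative_mask(100, 0, seed = 1), integer(0))
  expect_identical(sample_informative_mask(100, 1, seed = 1), 1:100)
  sizes <- vapply(1:1000, function(s) length(sample_informative_mask(100, 0.1, s)),
                  numeric(1))
  ## binomial mean 10, se of the Monte-Carlo mean ~0.095
  expect_lt(abs(mean(sizes) - 10), 0.5)
  expect_identical(sample_informative_mask(100, 0.1, seed = 7),
                   sample_informative_mask(100, 0.1, seed = 7))
})

test_that("informative features have equidistant group means, others none", {
  sizes <- balanced_group_sizes(300, 3)
  x <- generate_features(sizes, informative_idx = 1:3, mean_diff = 2, sd = 1e-4,
                         n_features = 6, seed = 3)
  groups <- rep(0:2, sizes)
  for (g in 0:2)
    expect_equal(mean(x[1, groups == g]), g * 2, tolerance = 1e-3)
  ## non-informative feature: identical distribution across groups
  x2 <- generate_features(sizes, 1:3, mean_diff = 0, sd = 1, n_features = 6, seed = 4)
  p <- t.test(x2[5, groups == 0], x2[5, groups == 2])$p.value
  expect_gt(p, 0.001)
  expect_error(generate_features(sizes, 1:3, 1, sd = -1, 6), "sd")
})

test_that("binary error injection hits the error-free and flipped corners", {
  truth <- rep(c(0L, 1L), each = 25)
  expect_identical(inject_binary_error(truth, 0, 1, seed = 1), truth)
  expect_identical(inject_binary_error(truth, 1, 0, seed = 1), 1L - truth)
  ## equal probabilities make the observed label independent of the truth
  cors <- vapply(1:300, function(s) {
    obs <- inject_binary_error(truth, 0.3, 0.3, seed = s)
    if (sd(obs) == 0) 0 else cor(truth, obs)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
  expect_error(inject_binary_error(c(0, 2), 0.1, 0.1), "binary")
})

test_that("graded error injection subtracts a Bernoulli draw in absolute value", {
  expect_identical(inject_graded_error(c(0L, 1L, 2L), 0, seed = 1), c(0L, 1L, 2L))
  expect_identical(inject_graded_error(c(0L, 1L, 2L), 1, seed = 1), c(1L, 0L, 1L))
  obs <- inject_graded_error(rep(3L, 4000), 0.5, seed = 2)
  expect_true(all(obs %in% c(2L, 3L)))
  expect_lt(abs(mean(obs == 2L) - 0.5), 0.05)
  expect_error(inject_graded_error(c(-1L, 0L), 0.5), "non-negative")
})

test_that("two-group semiquant ratings split the scale between the groups", {
  truth <- rep(c(0L, 1L), each = 10)
  r4 <- rate_semiquant(truth, 2, 4)
  expect_true(all(r4[truth == 0] %in% 0:1))
  expect_true(all(r4[truth == 1] %in% 2:3))
  r5 <- rate_semiquant(truth, 2, 5)
  expect_true(all(r5[truth == 0] %in% 0:1))
  expect_true(all(r5[truth == 1] %in% 2:4))
  ## identity when scale matches the groups
  expect_identical(rate_semiquant(rep(0:2, 5), 3, 3), rep(0:2, 5))
})

test_that("a simulated dataset is reproducible and respects the error-free corner", {
  cfg <- sim_config(50, 100, 2, 0.1, 1.5, 1, prob1 = 0, prob2 = 1,
                    encoding = "binary", seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$observed_labels, b$observed_labels)
  expect_identical(a$observed_labels, a$true_labels)
  expect_identical(table(a$true_labels), table(rep(0:1, each = 25)))
  expect_true(all(a$informative_idx %in% seq_len(100)))
  ## graded error-free corner
  cfg2 <- sim_config(50, 100, 2, 0.1, 1.5, 1, prob1 = 0, encoding = "semiquant",
                     n_categories = 4, seed = 12)
  d <- simulate_dataset(cfg2)
  expect_true(all(d$observed_labels %in% 0:3))
})

test_that("datasets round-trip through the delimited writer", {
  cfg <- sim_config(20, 15, 2, 0.2, 1, 1, prob1 = 0.1, prob2 = 0.9,
                    encoding = "binary", seed = 5)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_identical(back$true_labels, ds$true_labels)
  expect_identical(back$observed_labels, ds$observed_labels)
  expect_identical(back$informative_idx, ds$informative_idx)
})

test_that("non-informative features reject at roughly the nominal rate", {
  cfg <- sim_config(60, 200, 2, 0, 2, 1, prob1 = 0, prob2 = 1,
                    encoding = "binary", seed = 21)
  ds <- simulate_dataset(cfg)
  p <- vapply(seq_len(200), function(j)
    t.test(ds$features[j, ds$true_labels == 0],
           ds$features[j, ds$true_labels == 1])$p.value, numeric(1))
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.12)
})
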