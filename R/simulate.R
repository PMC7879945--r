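#' Simulation configuration
#'
#' Defines one simulated study: `n_samples` samples measured on `n_features`
#' features, a ground truth of `n_groups` normally distributed populations with
#' equidistant means (`mean_diff` between adjacent groups, common standard
#' deviation `sd`), a fraction `frac_informative` of features that actually
#' differ between groups, and an error-prone observed classification.
#'
#' The observed classification emulates a human rater. With
#' `encoding = "binary"` the observed label of a sample with true group 0 is
#' drawn as Bernoulli(`prob1`) and of true group 1 as Bernoulli(`prob2`), so
#' `prob1 = 0, prob2 = 1` is the error-free corner and `prob1 = 1, prob2 = 0`
#' a complete relabelling. With `encoding = "semiquant"` the rater scores on an
#' ordered integer scale with `n_categories` levels; a Bernoulli(`prob1`) draw
#' is subtracted from the true rating and the absolute value taken, so class 0
#' flips up to 1 and any class c >= 1 drops to c - 1.
#'
#' @param n_samples Total number of samples.
#' @param n_features Total number of features.
#' @param n_groups Number of true underlying populations (>= 2).
#' @param frac_informative Probability for each feature to be informative
#'   (associated with the true grouping); the realised informative set is a
#'   per-feature Bernoulli draw.
#' @param mean_diff Difference between the means of adjacent true groups.
#' @param sd Common standard deviation of all features.
#' @param prob1,prob2 Error probabilities of the observed classification (see
#'   Details); `prob2` is used by the binary encoding only.
#' @param encoding `"binary"` or `"semiquant"`.
#' @param n_categories Number of levels of the semi-quantitative rating scale;
#'   defaults to `n_groups`.
#' @param base_mean Mean of the lowest group (and of all non-informative
#'   features); only differences between groups matter for the method.
#' @param seed Master seed; per-stage sub-seeds (informative mask, feature
#'   values, label errors) are derived from it by fixed offsets.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_features, n_groups = 2L,
                       frac_informative = 0.1, mean_diff = 1, sd = 1,
                       prob1 = 0, prob2 = NULL,
                       encoding = c("binary", "semiquant"),
                       n_categories = NULL, base_mean = 0, seed = 1L) {
  encoding <- match.arg(encoding)
  if (!is_count(n_samples) || n_samples < 1) stopf("n_samples must be a positive count")
  if (!is_count(n_features) || n_features < 1) stopf("n_features must be a positive count")
  if (!is_count(n_groups) || n_groups < 2) stopf("n_groups must be an integer >= 2")
  if (n_groups > n_samples) stopf("invalid configuration: n_groups (%d) > n_samples (%d)",
                                  n_groups, n_samples)
  if (frac_informative < 0 || frac_informative > 1) stopf("frac_informative must lie in [0, 1]")
  if (!is.numeric(sd) || sd <= 0) stopf("invalid configuration: sd must be > 0")
  if (prob1 < 0 || prob1 > 1) stopf("prob1 must lie in [0, 1]")
  if (encoding == "binary") {
    if (n_groups != 2L) stopf("binary encoding requires n_groups = 2")
    if (is.null(prob2)) stopf("binary encoding requires prob2")
    if (prob2 < 0 || prob2 > 1) stopf("prob2 must lie in [0, 1]")
  }
  if (is.null(n_categories)) n_categories <- n_groups
  if (!is_count(n_categories) || n_categories < 2) stopf("n_categories must be an integer >= 2")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_groups = as.integer(n_groups),
                 frac_informative = frac_informative, mean_diff = mean_diff,
                 sd = sd, prob1 = prob1, prob2 = prob2, encoding = encoding,
                 n_categories = as.integer(n_categories),
                 base_mean = base_mean, seed = as.integer(seed)),
            class = "sim_config")
}

#' Balanced group sizes
#'
#' Splits `n_samples` into `n_groups` groups as evenly as possible; when an
#' even split is impossible the highest-ranked (last) group absorbs the
#' remainder.
#'
#' @param n_samples Total number of samples.
#' @param n_groups Number of groups.
#' @return Integer vector of length `n_groups` summing to `n_samples`.
#' @export
#' @examples
#' balanced_group_sizes(50, 3) # 16 16 18
balanced_group_sizes <- function(n_samples, n_groups) {
  if (!is_count(n_groups) || n_groups < 1) stopf("n_groups must be a positive count")
  if (!is_count(n_samples) || n_samples < n_groups)
    stopf("invalid configuration: n_samples (%s) < n_groups (%s)", n_samples, n_groups)
  base <- n_samples %/% n_groups
  sizes <- rep.int(base, n_groups)
  sizes[n_groups] <- n_samples - base * (n_groups - 1L)
  as.integer(sizes)
}

#' Sample the informative-feature mask
#'
#' Each feature is independently informative with probability `frac` (a
#' uniform draw below the threshold), so the realised number of informative
#' features is Binomial(`n_features`, `frac`).
#'
#' @param n_features Number of features.
#' @param frac Probability for a feature to be informative.
#' @param seed Seed for the uniform draws.
#' @return Sorted integer vector of informative feature indices (1-based).
#' @export
sample_informative_mask <- function(n_features, frac, seed = NULL) {
  if (frac < 0 || frac > 1) stopf("frac must lie in [0, 1]")
  u <- with_seed(seed, runif(n_features))
  which(u < frac)
}

#' Generate the feature matrix
#'
#' Informative features are drawn as Normal(`base_mean` + g * `mean_diff`,
#' `sd`) for a sample in true group g (groups 0-based); non-informative
#' features are drawn from Normal(`base_mean`, `sd`) common to all samples, so
#' selection difficulty is governed solely by `mean_diff`/`sd`.
#'
#' @param sizes Group sizes (samples ordered by group, lowest first).
#' @param informative_idx Indices of informative features (1-based).
#' @param mean_diff Mean difference between adjacent groups.
#' @param sd Common standard deviation (> 0).
#' @param n_features Number of features.
#' @param seed Seed for the normal draws.
#' @param base_mean Mean of the lowest group.
#' @return Numeric matrix, features in rows and samples in columns, with
#'   `feat<j>` / `smp<i>` dimnames.
#' @export
generate_features <- function(sizes, informative_idx, mean_diff, sd,
                              n_features, seed = NULL, base_mean = 0) {
  if (!is.numeric(sd) || sd <= 0) stopf("invalid configuration: sd must be > 0")
  n <- sum(sizes)
  groups <- rep.int(seq_along(sizes) - 1L, sizes)
  x <- with_seed(seed, matrix(rnorm(n_features * n, mean = 0, sd = sd),
                              nrow = n_features, ncol = n))
  shift <- matrix(0, nrow = n_features, ncol = n)
  if (length(informative_idx))
    shift[informative_idx, ] <- rep(groups * mean_diff, each = length(informative_idx))
  x <- x + shift + base_mean
  dimnames(x) <- list(paste0("feat", seq_len(n_features)), paste0("smp", seq_len(n)))
  x
}

#' Inject errors into a binary classification
#'
#' For a sample with true label 0 the observed label is Bernoulli(`prob1`);
#' for true label 1 it is Bernoulli(`prob2`), independently across samples.
#'
#' @param true_labels 0/1 vector of true group assignments.
#' @param prob1,prob2 Probability of observing a 1 for true label 0 / 1.
#' @param seed Seed for the Bernoulli draws.
#' @return 0/1 integer vector of observed labels.
#' @export
inject_binary_error <- function(true_labels, prob1, prob2, seed = NULL) {
  if (!all(true_labels %in% c(0, 1))) stopf("invalid input: labels must be binary 0/1")
  p <- ifelse(true_labels == 0, prob1, prob2)
  as.integer(with_seed(seed, rbinom(length(true_labels), 1L, p)))
}

#' Inject graded errors into a semi-quantitative classification
#'
#' A Bernoulli(`prob1`) draw is subtracted from each true rating and the
#' absolute value is used as the observed rating, so class 0 flips to 1 and
#' any class c >= 1 drops to c - 1 when an error occurs.
#'
#' @param labels Non-negative integer vector of true ratings.
#' @param prob1 Error probability.
#' @param seed Seed for the Bernoulli draws.
#' @return Integer vector of observed ratings.
#' @export
inject_graded_error <- function(labels, prob1, seed = NULL) {
  if (any(labels < 0) || any(labels != as.integer(labels)))
    stopf("invalid input: labels must be non-negative integers")
  e <- with_seed(seed, rbinom(length(labels), 1L, prob1))
  as.integer(abs(labels - e))
}

#' Map a dichotomous truth onto a semi-quantitative rating scale
#'
#' Emulates a rater who scores two true groups on a k-level ordinal scale:
#' group 0 samples are spread evenly over the lower `floor(k/2)` categories and
#' group 1 samples over the remaining ones (within-group allocation uses the
#' same balanced-split rule as the group sizes). When the number of groups
#' equals the number of categories the rating is the group index itself.
#'
#' @param true_labels Integer vector of true group indices (0-based).
#' @param n_groups Number of true groups.
#' @param n_categories Number of rating categories (>= `n_groups`).
#' @return Integer vector of error-free ratings in `0:(n_categories - 1)`.
#' @export
rate_semiquant <- function(true_labels, n_groups, n_categories) {
  if (n_categories < n_groups)
    stopf("n_categories (%d) must be >= n_groups (%d)", n_categories, n_groups)
  if (n_categories == n_groups) return(as.integer(true_labels))
  cat_per_group <- balanced_group_sizes(n_categories, n_groups)
  offsets <- c(0L, cumsum(cat_per_group))
  out <- integer(length(true_labels))
  for (g in seq_len(n_groups) - 1L) {
    idx <- which(true_labels == g)
    ncat <- cat_per_group[g + 1L]
    per_cat <- balanced_group_sizes(length(idx), min(ncat, length(idx)))
    cats <- offsets[g + 1L] + rep.int(seq_along(per_cat) - 1L, per_cat)
    out[idx] <- cats
  }
  out
}

#' Simulate a complete dataset
#'
#' Draws group sizes, the informative-feature mask, the feature matrix and the
#' error-prone observed classification for a [sim_config()]. The result is
#' bit-reproducible for a fixed config seed; the mask, features and label
#' errors use sub-seeds derived from it by fixed offsets so stages can be
#' regenerated independently.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_dataset` with elements `features` (matrix,
#'   features x samples), `true_labels`, `observed_labels`, `informative_idx`,
#'   `sizes` and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- balanced_group_sizes(config$n_samples, config$n_groups)
  true_labels <- rep.int(seq_along(sizes) - 1L, sizes)
  informative_idx <- sample_informative_mask(config$n_features, config$frac_informative,
                                             derive_seed(config$seed, 1L))
  features <- generate_features(sizes, informative_idx, config$mean_diff, config$sd,
                                config$n_features, derive_seed(config$seed, 2L),
                                config$base_mean)
  observed <- if (config$encoding == "binary") {
    inject_binary_error(true_labels, config$prob1, config$prob2,
                        derive_seed(config$seed, 3L))
  } else {
    rating <- rate_semiquant(true_labels, config$n_groups, config$n_categories)
    inject_graded_error(rating, config$prob1, derive_seed(config$seed, 3L))
  }
  structure(list(features = features, true_labels = as.integer(true_labels),
                 observed_labels = observed, informative_idx = informative_idx,
                 sizes = sizes, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("sim_dataset: %d features x %d samples, %d true groups (%s encoding)\n",
              cfg$n_features, cfg$n_samples, cfg$n_groups, cfg$encoding))
  cat(sprintf("  informative features: %d (frac = %.2f), mean_diff = %g, sd = %g\n",
              length(x$informative_idx), cfg$frac_informative, cfg$mean_diff, cfg$sd))
  cat(sprintf("  label error probs: prob1 = %g%s; %d samples with observed != true\n",
              cfg$prob1, if (!is.null(cfg$prob2)) sprintf(", prob2 = %g", cfg$prob2) else "",
              sum(x$observed_labels != x$true_labels)))
  invisible(x)
}

#' Write / read a simulated dataset as delimited text
#'
#' `write_dataset()` stores `features.tsv` (features in rows, samples in
#' columns, feature IDs in the first column), `meta.tsv` (one row per sample
#' with `true_label` and `observed_label`) and a `config.json` sidecar.
#' `read_dataset()` restores the dataset from such a directory.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output / input directory.
#' @return `write_dataset()` the directory invisibly; `read_dataset()` a
#'   `sim_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat <- data.frame(feature_id = rownames(dataset$features),
                     dataset$features, check.names = FALSE)
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(dataset$features),
                     true_label = dataset$true_labels,
                     observed_label = dataset$observed_labels)
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  cfg$informative_idx <- dataset$informative_idx
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  feat <- read.table(file.path(dir, "features.tsv"), header = TRUE, sep = "\t",
                     check.names = FALSE)
  m <- as.matrix(feat[, -1, drop = FALSE])
  rownames(m) <- feat[[1]]
  meta <- read.table(file.path(dir, "meta.tsv"), header = TRUE, sep = "\t")
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  informative <- as.integer(cfg$informative_idx)
  cfg$informative_idx <- NULL
  config <- do.call(sim_config, cfg[!vapply(cfg, is.null, logical(1))])
  structure(list(features = m, true_labels = as.integer(meta$true_label),
                 observed_labels = as.integer(meta$observed_label),
                 informative_idx = informative,
                 sizes = as.integer(table(meta$true_label)), config = config),
            class = "sim_dataset")
}
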