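## ---- evaluation against the ground truth ----------------------------------
##
## Model scores are compared against the error-free group assignment (never
## used for training) by rank-based AUC: the Mann-Whitney probability that a
## random positive outranks a random negative, ties counted 1/2. Orientation
## is explicit: "fixed" keeps higher-score-means-higher-class (so AUCs below
## 0.5 are reported as such), "auto" flips by comparing class medians -- the
## ROC-package convention the benchmark uses, which usually re-orients
## anti-correlated scores but can still yield AUCs below 0.5 when the median
## heuristic and the pairwise ordering disagree.

auc_mann_whitney <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Binary AUC
#'
#' @param scores Numeric score vector.
#' @param truth 0/1 ground-truth labels; both classes must be present.
#' @param direction `"fixed"`: higher score means class 1, never flipped, so
#'   values below 0.5 are reportable. `"auto"`: if the median score of class 1
#'   is below that of class 0 the orientation is flipped (median-based ROC
#'   convention).
#' @return AUC in `[0, 1]`.
#' @export
auc_binary <- function(scores, truth, direction = c("fixed", "auto")) {
  direction <- match.arg(direction)
  if (!all(truth %in% c(0, 1))) stopf("truth must be a 0/1 vector")
  if (length(unique(truth)) < 2L) stopf("undefined AUC: single-class truth")
  if (length(scores) != length(truth)) stopf("scores and truth lengths differ")
  a <- auc_mann_whitney(scores, truth == 1)
  if (direction == "auto" &&
      median(scores[truth == 1]) < median(scores[truth == 0])) a <- 1 - a
  a
}

#' Multiclass AUC (Hand-Till style, single score vector)
#'
#' Unweighted mean over all unordered class pairs of the pairwise binary AUC
#' computed on the score vector restricted to the two classes, the higher
#' class playing the positive role. For exactly two classes this reduces to
#' [auc_binary()]. With `direction = "auto"` each pairwise AUC is oriented by
#' the median rule separately, matching the behaviour of the standard
#' multiclass-ROC tools for a one-dimensional predictor.
#'
#' @param scores Numeric score vector.
#' @param truth Integer class labels; at least two classes must be present.
#' @inheritParams auc_binary
#' @return Mean pairwise AUC in `[0, 1]`.
#' @export
auc_multiclass <- function(scores, truth, direction = c("fixed", "auto")) {
  direction <- match.arg(direction)
  classes <- sort(unique(truth))
  if (length(classes) < 2L) stopf("undefined AUC: fewer than two classes present")
  pairs <- utils::combn(classes, 2)
  mean(apply(pairs, 2, function(cl) {
    keep <- truth %in% cl
    auc_binary(scores[keep], as.integer(truth[keep] == cl[2]), direction)
  }))
}

#' AUC for a two-or-more-class ground truth
#'
#' Convenience dispatcher used by the benchmark: [auc_binary()] when the truth
#' has two classes, [auc_multiclass()] otherwise.
#'
#' @inheritParams auc_multiclass
#' @export
evaluate_auc <- function(scores, truth, direction = c("fixed", "auto")) {
  direction <- match.arg(direction)
  classes <- sort(unique(truth))
  if (length(classes) == 2L)
    auc_binary(scores, as.integer(truth == classes[2]), direction)
  else
    auc_multiclass(scores, truth, direction)
}

#' AUC ranks across pipeline variants
#'
#' Ranks the AUCs of competing pipeline variants within each matched
#' condition. Ties are resolved by mean rank (`"average"`) or by a seeded
#' random permutation (`"random"`, each integer rank used exactly once).
#'
#' @param auc Numeric matrix of AUCs, conditions in rows and variants in
#'   columns (a vector is treated as a single condition); missing values
#'   (failed fits) keep rank `NA`.
#' @param tie_method `"average"` or `"random"`.
#' @param seed Seed for the random tie resolution.
#' @return Matrix (or vector) of ranks, same shape as `auc`; higher AUC gets
#'   the higher rank.
#' @export
auc_ranks <- function(auc, tie_method = c("average", "random"), seed = NULL) {
  tie_method <- match.arg(tie_method)
  vec_in <- is.null(dim(auc))
  m <- if (vec_in) matrix(auc, nrow = 1) else as.matrix(auc)
  out <- with_seed(if (tie_method == "random") seed else NULL,
    t(apply(m, 1, function(row)
      rank(row, ties.method = if (tie_method == "average") "average" else "random",
           na.last = "keep"))))
  if (vec_in) as.numeric(out) else structure(out, dimnames = dimnames(m))
}
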