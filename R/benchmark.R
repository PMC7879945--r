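## ---- simulation benchmark -------------------------------------------------
##
## Reproduces the simulation study: for every condition (prob pair x effect
## size x scale axes) both pre-filtering variants are run on the same
## simulated dataset, final models are trained on the observed (noisy) labels
## and evaluated by AUC against the true grouping. The effect grids are
## reconstructions (the published work does not print them), chosen against
## the reported qualitative behaviour of each scenario: for the binary
## scenarios mean differences {1, 1.5, 2.5} by standard deviations
## {1, 1.5, 2}, so that weakly informative label-error pairs sit below the
## multiplicity-adjusted detection threshold while strongly informative
## pairs clear it; for the semi-quantitative scenarios (where graded errors
## leave the labels informative at every error level, so effect size alone
## governs detection) the weaker grid {0.4, 0.8, 1.2} x {1, 1.5, 2},
## consistent with the reported relative fit fractions; and for the
## graduated scenario, where the class spread grows with the number of
## groups, the still-smaller per-class differences {0.25, 0.45, 0.8}.
## All presets are fully overridable via `effect_grid`.

default_effect_grid <- function() {
  expand.grid(mean_diff = c(1, 1.5, 2.5), sd = c(1, 1.5, 2))
}

semiquant_effect_grid <- function() {
  expand.grid(mean_diff = c(0.4, 0.8, 1.2), sd = c(1, 1.5, 2))
}

#' Benchmark grid configurations
#'
#' `grid_config()` assembles a benchmark grid; the `preset_*()` constructors
#' return the study designs evaluated in the package's simulation benchmark:
#'
#' * `preset_binary_two_group()`: two true groups, binary rating, 25
#'   samples/group, 100 features, all 16 ordered `(prob1, prob2)` pairs from
#'   `{0.1, 0.3, 0.6, 0.9}`, 3x3 effect grid (144 conditions).
#' * `preset_semiquant_two_group()`: two true groups rated on a 3-5 level
#'   scale with graded errors, 50 samples, 100 features.
#' * `preset_semiquant_graduated()`: 3-10 true graduated groups rated on the
#'   matching scale with graded errors, 50 samples, 100 features.
#' * `preset_binary_scaled()`: the larger binary design, reduced for a
#'   single workstation (2,000 features, 50 samples/group, error
#'   probabilities in `{0.1, 0.3}`, a 3x2 effect grid, Bonferroni
#'   adjustment).
#'
#' @param scenario One of `"binary_2group"`, `"semiquant_2group"`,
#'   `"semiquant_kgroup"`.
#' @param n_samples_per_group Samples per true group (vector allowed).
#' @param n_features Number of features (vector allowed).
#' @param prob_grid Data frame with columns `prob1` and (binary scenario)
#'   `prob2`.
#' @param effect_grid Data frame with columns `mean_diff` and `sd`.
#' @param categories Rating-scale sizes (semi-quantitative scenarios); for
#'   `"semiquant_kgroup"` these are also the numbers of true groups.
#' @param adjustments Multiplicity adjustments to run the inverted-role
#'   variant (V1) with.
#' @param replicates Seeded replicates per condition.
#' @param frac_informative Fraction of informative features.
#' @param master_seed Master seed; every condition/replicate derives its own
#'   sub-seed from it.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(scenario = c("binary_2group", "semiquant_2group",
                                     "semiquant_kgroup"),
                        n_samples_per_group = 25L, n_features = 100L,
                        prob_grid = NULL, effect_grid = default_effect_grid(),
                        categories = NULL, adjustments = "BH",
                        replicates = 1L, frac_informative = 0.1,
                        master_seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(prob_grid)) {
    probs <- c(0.1, 0.3, 0.6, 0.9)
    prob_grid <- if (scenario == "binary_2group")
      expand.grid(prob1 = probs, prob2 = probs) else data.frame(prob1 = probs)
  }
  if (is.null(categories))
    categories <- switch(scenario, binary_2group = 2L,
                         semiquant_2group = 3:5, semiquant_kgroup = 3:10)
  stopifnot(nrow(prob_grid) > 0, nrow(effect_grid) > 0,
            all(unlist(prob_grid[c("prob1", intersect("prob2", names(prob_grid)))]) >= 0),
            all(unlist(prob_grid[c("prob1", intersect("prob2", names(prob_grid)))]) <= 1),
            all(adjustments %in% c("BH", "bonferroni", "holm", "none")))
  structure(list(scenario = scenario,
                 n_samples_per_group = as.integer(n_samples_per_group),
                 n_features = as.integer(n_features), prob_grid = prob_grid,
                 effect_grid = effect_grid, categories = as.integer(categories),
                 adjustments = adjustments, replicates = as.integer(replicates),
                 frac_informative = frac_informative,
                 master_seed = as.integer(master_seed)),
            class = "grid_config")
}

#' @rdname grid_config
#' @param ... Overrides passed on to `grid_config()`.
#' @export
preset_binary_two_group <- function(...) {
  grid_config(scenario = "binary_2group", n_samples_per_group = 25L,
              n_features = 100L, adjustments = c("BH", "bonferroni"), ...)
}

#' @rdname grid_config
#' @export
preset_semiquant_two_group <- function(effect_grid = semiquant_effect_grid(), ...) {
  grid_config(scenario = "semiquant_2group", n_samples_per_group = 25L,
              n_features = 100L, adjustments = "BH",
              effect_grid = effect_grid, ...)
}

#' @rdname grid_config
#' @export
preset_semiquant_graduated <- function(effect_grid = expand.grid(mean_diff = c(0.25, 0.45, 0.8),
                                                                 sd = c(1, 1.5, 2)), ...) {
  grid_config(scenario = "semiquant_kgroup", n_samples_per_group = NA,
              effect_grid = effect_grid, ...)
}

#' @rdname grid_config
#' @export
preset_binary_scaled <- function(effect_grid = expand.grid(mean_diff = c(1, 1.5, 2.5),
                                                           sd = c(1, 2)), ...) {
  grid_config(scenario = "binary_2group", n_samples_per_group = 50L,
              n_features = 2000L,
              prob_grid = expand.grid(prob1 = c(0.1, 0.3), prob2 = c(0.1, 0.3)),
              effect_grid = effect_grid,
              adjustments = "bonferroni", ...)
}

## Enumerate all conditions of a grid as a data frame (deterministic order).
make_conditions <- function(grid) {
  ax <- list(eff = seq_len(nrow(grid$effect_grid)),
             prob = seq_len(nrow(grid$prob_grid)),
             cat = grid$categories,
             npg = grid$n_samples_per_group,
             nf = grid$n_features)
  cond <- expand.grid(ax, KEEP.OUT.ATTRS = FALSE)
  k_groups <- if (grid$scenario == "semiquant_kgroup") cond$cat else 2L
  npg <- cond$npg
  if (grid$scenario == "semiquant_kgroup") {
    ## fixed total sample number; groups share it via the balanced-split rule
    npg <- ifelse(is.na(npg), NA, npg)
  }
  n_samples <- ifelse(is.na(npg), 50L, npg * k_groups)
  out <- data.frame(
    scenario = grid$scenario,
    n_samples = as.integer(n_samples),
    n_features = as.integer(cond$nf),
    n_groups = as.integer(k_groups),
    n_categories = as.integer(cond$cat),
    prob1 = grid$prob_grid$prob1[cond$prob],
    prob2 = if ("prob2" %in% names(grid$prob_grid))
      grid$prob_grid$prob2[cond$prob] else NA_real_,
    mean_diff = grid$effect_grid$mean_diff[cond$eff],
    sd = grid$effect_grid$sd[cond$eff])
  out$condition_id <- sprintf("%s_c%03d", grid$scenario, seq_len(nrow(out)))
  out
}

condition_config <- function(cond, grid, seed) {
  sim_config(n_samples = cond$n_samples, n_features = cond$n_features,
             n_groups = cond$n_groups,
             frac_informative = grid$frac_informative,
             mean_diff = cond$mean_diff, sd = cond$sd,
             prob1 = cond$prob1,
             prob2 = if (is.na(cond$prob2)) NULL else cond$prob2,
             encoding = if (cond$scenario == "binary_2group") "binary" else "semiquant",
             n_categories = cond$n_categories, seed = seed)
}

#' Run one benchmark condition
#'
#' Simulates a dataset, applies one pre-filtering variant (`"V1"` inverted
#' roles with the given multiplicity adjustment, `"V2"` standard CV ranking),
#' trains the final model on the observed labels (logistic for binary,
#' linear for semi-quantitative ratings) with backward stepwise reduction,
#' and evaluates the model scores by AUC against the true grouping. Any stage
#' failure the study counts as "no model" (no significant feature, a single
#' observed class, non-convergence) yields `success = FALSE`.
#'
#' @param config A [sim_config()] (or a pre-simulated `sim_dataset`).
#' @param variant `"V1"` or `"V2"`.
#' @param adjustment Multiplicity adjustment for V1.
#' @param seed Seed for the CV fold assignments of the variant.
#' @param direction AUC orientation handed to [evaluate_auc()]; the benchmark
#'   default is the median-based `"auto"` ROC convention.
#' @param criterion Stepwise criterion, see [stepwise_backward()].
#' @param alpha Adjusted-p cutoff for V1.
#' @return One-row data frame (a benchmark record) with the condition
#'   parameters, `success`, `n_significant`, `n_selected`, `n_terms`, `auc`
#'   and the elapsed `seconds`.
#' @export
run_condition <- function(config, variant = c("V1", "V2"), adjustment = "BH",
                          seed = NULL, direction = "auto", criterion = "AIC",
                          alpha = 0.05) {
  variant <- match.arg(variant)
  dataset <- if (inherits(config, "sim_dataset")) config else simulate_dataset(config)
  cfg <- dataset$config
  binary <- cfg$encoding == "binary"
  family <- if (binary) "logistic" else "gaussian"
  t0 <- proc.time()[["elapsed"]]
  n_significant <- NA_integer_
  n_selected <- 0L
  n_terms <- NA_integer_
  auc <- NA_real_
  success <- FALSE
  res <- tryCatch({
    selected <- if (variant == "V1") {
      pf <- prefilter(dataset$features, dataset$observed_labels,
                      adjust = adjustment, alpha = alpha,
                      seed = derive_seed(seed, 11L))
      n_significant <- length(pf$significant_idx)
      pf$selected_idx
    } else {
      rk <- baseline_rank(dataset$features, dataset$observed_labels,
                          type = if (binary) "lr" else "lm",
                          n_select = cfg$n_samples,
                          seed = derive_seed(seed, 12L))
      rk$selected_idx
    }
    n_selected <- length(selected)
    if (variant == "V1" && length(selected) == 0L) stopf("no significant features")
    X <- t(dataset$features[selected, , drop = FALSE])
    full <- suppressWarnings(fit_glm(X, dataset$observed_labels, family))
    model <- suppressWarnings(stepwise_backward(full, criterion = criterion,
                                                seed = derive_seed(seed, 13L)))
    ## a perfect-separation / saturated fit (zero deviance) counts as fitted,
    ## mirroring stepwise selection on top of standard GLM fits; only genuine
    ## non-convergence (iteration cap without a stable fit) fails
    if (!model$converged && !model$degenerate) stopf("final model did not converge")
    n_terms <- length(model$terms)
    scores <- predict_scores(model, t(dataset$features))
    auc <- evaluate_auc(scores, dataset$true_labels, direction = direction)
    TRUE
  }, error = function(e) FALSE)
  success <- isTRUE(res)
  data.frame(scenario = cfg$encoding, n_samples = cfg$n_samples,
             n_features = cfg$n_features, n_groups = cfg$n_groups,
             n_categories = cfg$n_categories, prob1 = cfg$prob1,
             prob2 = if (is.null(cfg$prob2)) NA_real_ else cfg$prob2,
             mean_diff = cfg$mean_diff, sd = cfg$sd,
             variant = variant,
             adjustment = if (variant == "V1") adjustment else "none",
             success = success, n_significant = n_significant,
             n_selected = n_selected, n_terms = n_terms,
             auc = if (success) auc else NA_real_,
             seconds = proc.time()[["elapsed"]] - t0)
}

#' Run a full benchmark grid
#'
#' Enumerates all conditions of a [grid_config()] deterministically, derives a
#' per-condition/replicate sub-seed from the master seed, simulates one
#' dataset per condition x replicate, and runs V1 (once per adjustment) and V2
#' on that same dataset. Identical master seeds give identical tables.
#'
#' @param grid A [grid_config()].
#' @param direction AUC orientation (see [run_condition()]).
#' @param out_file Optional TSV path; records are appended condition by
#'   condition, so partial results survive an interruption.
#' @param progress Print one structured log line per record.
#' @return Data frame of benchmark records, one row per condition x replicate
#'   x variant (x adjustment for V1), with `condition_id` and `replicate`.
#' @export
run_grid <- function(grid, direction = "auto", out_file = NULL, progress = FALSE) {
  stopifnot(inherits(grid, "grid_config"))
  conds <- make_conditions(grid)
  rows <- vector("list", nrow(conds) * grid$replicates * (length(grid$adjustments) + 1L))
  k <- 0L
  for (i in seq_len(nrow(conds))) {
    for (rep_i in seq_len(grid$replicates)) {
      seed <- derive_seed(grid$master_seed, i * 1009L + rep_i)
      config <- condition_config(conds[i, ], grid, seed)
      dataset <- simulate_dataset(config)
      recs <- c(lapply(grid$adjustments, function(adj)
                  run_condition(dataset, "V1", adjustment = adj, seed = seed,
                                direction = direction)),
                list(run_condition(dataset, "V2", seed = seed,
                                   direction = direction)))
      for (r in recs) {
        r$condition_id <- conds$condition_id[i]
        r$replicate <- rep_i
        r$seed <- seed
        k <- k + 1L
        rows[[k]] <- r
        if (progress)
          message(sprintf("[%s rep%d] %s/%s success=%s auc=%s (%.2fs)",
                          r$condition_id, rep_i, r$variant, r$adjustment,
                          r$success, ifelse(is.na(r$auc), "NA", sprintf("%.3f", r$auc)),
                          r$seconds))
        if (!is.null(out_file))
          write.table(r, out_file, sep = "\t", quote = FALSE, row.names = FALSE,
                      col.names = !file.exists(out_file), append = file.exists(out_file))
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

## Paired V1/V2 AUC matrix for rank statistics: one row per
## condition x replicate, one column per variant/adjustment pipeline.
paired_auc <- function(records) {
  records$pipeline <- ifelse(records$variant == "V2", "V2",
                             paste0("V1_", records$adjustment))
  key <- interaction(records$condition_id, records$replicate, drop = TRUE)
  pipes <- sort(unique(records$pipeline))
  m <- matrix(NA_real_, nlevels(key), length(pipes),
              dimnames = list(levels(key), pipes))
  m[cbind(as.integer(key), match(records$pipeline, pipes))] <- records$auc
  m
}

#' Summarise a benchmark table
#'
#' Per pipeline (V1 per adjustment, V2): number and fraction of successful
#' fits, the successful-fit fraction relative to V2, median and range of the
#' AUC over successful fits, count and fraction of models with AUC <= 0.5
#' (inclusive), and median AUC ranks across pipelines under both tie methods.
#'
#' @param records Data frame from [run_grid()].
#' @param strata Optional column name (e.g. `"n_categories"`); adds a
#'   per-stratum table with the same statistics. Strata with zero successful
#'   fits report `NA` AUC summaries, not zeros.
#' @param seed Seed for the random tie method.
#' @return List with elements `overall` (data frame) and, if requested,
#'   `by_stratum`.
#' @export
summarize_benchmark <- function(records, strata = NULL, seed = 1L) {
  one <- function(recs) {
    recs$pipeline <- ifelse(recs$variant == "V2", "V2",
                            paste0("V1_", recs$adjustment))
    pa <- paired_auc(recs)
    rk_avg <- auc_ranks(pa, "average")
    rk_rnd <- auc_ranks(pa, "random", seed = seed)
    n_v2 <- sum(recs$success[recs$pipeline == "V2"])
    do.call(rbind, lapply(sort(unique(recs$pipeline)), function(p) {
      r <- recs[recs$pipeline == p, ]
      aucs <- r$auc[r$success]
      data.frame(pipeline = p, n_conditions = nrow(r), n_success = sum(r$success),
                 fit_fraction = mean(r$success),
                 fit_vs_v2 = if (n_v2 > 0) sum(r$success) / n_v2 else NA_real_,
                 median_auc = if (length(aucs)) median(aucs) else NA_real_,
                 min_auc = if (length(aucs)) min(aucs) else NA_real_,
                 max_auc = if (length(aucs)) max(aucs) else NA_real_,
                 n_auc_le_half = sum(aucs <= 0.5),
                 frac_auc_le_half = if (length(aucs)) mean(aucs <= 0.5) else NA_real_,
                 median_rank_avg = median(rk_avg[, p], na.rm = TRUE),
                 median_rank_rnd = median(rk_rnd[, p], na.rm = TRUE))
    }))
  }
  out <- list(overall = one(records))
  if (!is.null(strata)) {
    sp <- split(records, records[[strata]])
    by_stratum <- do.call(rbind, lapply(names(sp), function(s) {
      df <- one(sp[[s]])
      df[[strata]] <- s
      df
    }))
    out$by_stratum <- by_stratum
  }
  out
}
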