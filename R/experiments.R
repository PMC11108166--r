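#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the values with replacement `B` times and returns the
#' 2.5th/97.5th (for `level = 0.95`) percentiles of the resampled means.
#' Used to put dataset-ensemble means (scores, probabilities) on a
#' defensible uncertainty footing.
#'
#' @param values non-empty numeric vector.
#' @param level confidence level (default 0.95).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return Numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, B = 1000, seed = 1L) {
  n <- length(values)
  if (n == 0) {
    rncv_stop("values must be non-empty", "rncv_invalid_input")
  }
  if (!is_count(B) || B < 1) {
    rncv_stop("B must be >= 1", "rncv_config_error")
  }
  means <- with_seed(seed, {
    colMeans(matrix(values[sample.int(n, n * B, replace = TRUE)], n, B))
  })
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha)))
}

#' Ensemble sweep over dataset sizes, metrics and permutation counts
#'
#' Generates `datasets_per_size` synthetic Gaussian datasets per size,
#' runs one shared-permutation test per (dataset, metric) with
#' `max(permutation_counts)` permutations, and derives the probability
#' for every smaller count from the leading permutations of that same
#' ensemble (all counts therefore see identical data). Scores are
#' normalised onto `[0, 1]`; per (size, metric, count) cell the table
#' carries the ensemble mean and percentile-bootstrap CI of the
#' normalised score and of the probability.
#'
#' @param sizes dataset sizes to sweep.
#' @param datasets_per_size replicates per size.
#' @param metrics metric ids to evaluate (training metric = evaluation
#'   metric throughout).
#' @param permutation_counts permutation counts to compare.
#' @param cfg an [pipeline_config()].
#' @param grid an [svm_grid()] or `NULL` for the default.
#' @param n_outer,k_inner,repeat_seeds CV geometry, as in
#'   [repeated_nested_cv()].
#' @param class2_mean mean shift of the generated class 2 (default 0.2;
#'   0 gives null data).
#' @param n_features generated feature count (default 10).
#' @param seed master seed; every dataset, fold and permutation derives
#'   from it.
#' @param bootstrap_B bootstrap resamples for the CIs.
#' @param out_csv optional path; the tidy table is written as CSV.
#' @param verbose print one line per dataset as results arrive.
#' @return A data frame, one row per size x metric x permutation count.
#' @export
run_sweep <- function(sizes, datasets_per_size, metrics = "mcc",
                      permutation_counts = 25,
                      cfg = pipeline_config(), grid = NULL,
                      n_outer = 10, k_inner = 5, repeat_seeds = 1:5,
                      class2_mean = 0.2, n_features = 10, seed = 1L,
                      bootstrap_B = 1000, out_csv = NULL,
                      verbose = FALSE) {
  stopifnot(length(sizes) > 0, length(metrics) > 0,
            length(permutation_counts) > 0)
  for (m in metrics) check_metric(m)
  n_max <- max(permutation_counts)
  ens <- generate_ensemble(sizes, datasets_per_size,
                           n_features = n_features,
                           class2_mean = class2_mean,
                           seed = derive_seed(seed, 1))
  size_of <- rep(sizes, each = datasets_per_size)
  score_norm <- array(NA_real_, c(length(ens), length(metrics)))
  probs <- array(NA_real_,
                 c(length(ens), length(metrics),
                   length(permutation_counts)))
  for (d in seq_along(ens)) {
    perms <- make_permutations(ens[[d]], n_max, derive_seed(seed, 2, d))
    for (mi in seq_along(metrics)) {
      pt <- permutation_test(ens[[d]], cfg, grid, metrics[mi], n_outer,
                             k_inner, repeat_seeds,
                             permutations = perms)
      score_norm[d, mi] <- normalise_score(metrics[mi],
                                           pt$original$mean_score)
      for (ni in seq_along(permutation_counts)) {
        probs[d, mi, ni] <- empirical_probability(
          pt$original$mean_score,
          pt$permuted_rncv_scores[seq_len(permutation_counts[ni])])
      }
    }
    if (verbose) {
      message(sprintf("dataset %d/%d (%s) done", d, length(ens),
                      ens[[d]]$name))
    }
  }
  rows <- list()
  for (si in seq_along(sizes)) {
    in_size <- size_of == sizes[si]
    for (mi in seq_along(metrics)) {
      for (ni in seq_along(permutation_counts)) {
        sc <- score_norm[in_size, mi]
        pb <- probs[in_size, mi, ni]
        ci_s <- bootstrap_ci(sc, B = bootstrap_B,
                             seed = derive_seed(seed, 3, si, mi, ni))
        ci_p <- bootstrap_ci(pb, B = bootstrap_B,
                             seed = derive_seed(seed, 4, si, mi, ni))
        rows[[length(rows) + 1]] <- data.frame(
          size = sizes[si], metric = metrics[mi],
          n_permutations = permutation_counts[ni],
          mean_score_norm = mean(sc), score_ci_lower = ci_s[1],
          score_ci_upper = ci_s[2], mean_probability = mean(pb),
          prob_ci_lower = ci_p[1], prob_ci_upper = ci_p[2],
          n_datasets = sum(in_size))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE)
  }
  out
}

#' Ablation study of the pipeline components on one dataset
#'
#' Evaluates the four [ablation_variants()] (full pipeline, no feature
#' selection, no hyperparameter tuning, neither) with
#' [permutation_test()], all four sharing the identical permuted label
#' sets so that score and probability differences are attributable to
#' the ablated component alone.
#'
#' @inheritParams permutation_test
#' @param base_cfg configuration whose non-flag settings all variants
#'   share.
#' @return A data frame with one row per variant: score, score spread
#'   across repeats, `p_rncv` and `p_ncv_averaged`. The shared permuted
#'   label sets are attached as attribute `permutation_labels`.
#' @export
run_ablation <- function(ds, base_cfg = pipeline_config(), grid = NULL,
                         metric = "mcc", n_outer = 10, k_inner = 5,
                         repeat_seeds = 1:5, n_permutations = 25,
                         seed = 1L) {
  perms <- make_permutations(ds, n_permutations, seed)
  variants <- ablation_variants(base_cfg)
  rows <- lapply(names(variants), function(v) {
    grid_v <- grid
    if (!is.null(grid_v) && !variants[[v]]$use_feature_selection) {
      grid_v$n_features_to_select <- NULL  # not tuned in this variant
    }
    pt <- permutation_test(ds, variants[[v]], grid_v, metric, n_outer,
                           k_inner, repeat_seeds, permutations = perms)
    cbind(data.frame(variant = v), compare_ncv_vs_rncv(pt))
  })
  out <- do.call(rbind, rows)
  attr(out, "permutation_labels") <- do.call(rbind, lapply(perms,
    function(p) as.integer(p$labels)))
  out
}

#' Multi-metric evaluation report for one dataset
#'
#' Runs one repeated-nested-CV permutation test per metric (the training
#' metric always equals the evaluation metric), with the same repeat
#' seeds and the same permuted label sets across metrics, and tabulates
#' raw and normalised scores, probabilities and the averaged confusion
#' matrix per metric.
#'
#' @inheritParams permutation_test
#' @param metrics metric ids to report (default: all eight).
#' @return A data frame with one row per metric.
#' @export
compare_metrics_report <- function(ds, metrics = METRIC_IDS,
                                   cfg = pipeline_config(), grid = NULL,
                                   n_outer = 10, k_inner = 5,
                                   repeat_seeds = 1:5,
                                   n_permutations = 50, seed = 1L) {
  for (m in metrics) check_metric(m)
  perms <- make_permutations(ds, n_permutations, seed)
  rows <- lapply(metrics, function(m) {
    pt <- permutation_test(ds, cfg, grid, m, n_outer, k_inner,
                           repeat_seeds, permutations = perms)
    cm <- pt$original$confusion
    data.frame(metric = m, score = pt$original$mean_score,
               score_norm = normalise_score(m, pt$original$mean_score),
               p_rncv = pt$p_rncv,
               p_ncv_averaged = pt$p_ncv_averaged,
               tp = cm[["tp"]], fp = cm[["fp"]], fn = cm[["fn"]],
               tn = cm[["tn"]])
  })
  do.call(rbind, rows)
}
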