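#' Empirical probability of the null hypothesis
#'
#' Add-one permutation p-value: with `N` permuted scores, the probability
#' is `(1 + #\{permuted >= original\}) / (1 + N)`. Ties count against the
#' original score, and the original counts as one member of the null
#' ensemble, so the probability can never reach 0 -- the floor is
#' `1 / (N + 1)` (2% at two-decimal reporting with 50 permutations).
#'
#' @param original_score score on the unpermuted data.
#' @param permuted_scores non-empty vector of scores on label-permuted
#'   data.
#' @return The empirical probability, a multiple of `1 / (N + 1)`.
#' @export
empirical_probability <- function(original_score, permuted_scores) {
  n <- length(permuted_scores)
  if (n == 0) {
    rncv_stop("permuted_scores must be non-empty", "rncv_invalid_input")
  }
  (1 + sum(permuted_scores >= original_score)) / (1 + n)
}

# Draw the N whole-dataset label permutations shared by every evaluation
# of one test.
make_permutations <- function(ds, n_permutations, seed) {
  lapply(seq_len(n_permutations), function(j) {
    permute_labels(ds, derive_seed(seed, 7, j))
  })
}

#' Shared-permutation significance test for rnCV and nCV scores
#'
#' Estimates the probability that the evaluated score would arise with no
#' exploitable feature-label dependency. `n_permutations` label-permuted
#' copies of the dataset are drawn once (class counts, and hence
#' stratification feasibility, are preserved); the original data and
#' every permuted copy are evaluated with [repeated_nested_cv()] under
#' the *same* repeat seeds and fold machinery. Three probabilities are
#' derived from this single shared set of permutations, so any difference
#' between them reflects only the aggregation method:
#' \describe{
#'   \item{`p_rncv`}{original rnCV mean vs the permuted rnCV means.}
#'   \item{`p_ncv_per_seed`}{for each repeat seed, the original nCV score
#'     vs the permuted nCV scores of that same seed.}
#'   \item{`p_ncv_averaged`}{mean of the per-seed probabilities.}
#' }
#' Averaging scores before comparison (rnCV) damps the fold-draw noise on
#' both sides, so `p_rncv` is typically at or below `p_ncv_averaged`.
#' Small permutation counts overestimate the probability; 25-100 suit
#' qualitative work, while publication-grade p-values call for 999+.
#'
#' @inheritParams repeated_nested_cv
#' @param n_permutations number of label permutations `N` (>= 1).
#' @param seed master seed for the permutation draws.
#' @param permutations optionally, a pre-drawn list of permuted datasets
#'   (as from several calls sharing one null ensemble); overrides
#'   `n_permutations`.
#' @param keep_permuted retain the full per-permutation `rncv_rncv`
#'   objects (default `FALSE`; scores are always retained).
#' @return An object of class `rncv_permtest`.
#' @export
permutation_test <- function(ds, cfg = pipeline_config(), grid = NULL,
                             metric = "mcc", n_outer = 10, k_inner = 5,
                             repeat_seeds = 1:5, n_permutations = 50,
                             seed = 1L, permutations = NULL,
                             keep_permuted = FALSE) {
  stopifnot(inherits(ds, "rncv_dataset"))
  if (is.null(permutations)) {
    if (!is_count(n_permutations) || n_permutations < 1) {
      rncv_stop("n_permutations must be >= 1", "rncv_config_error")
    }
    permutations <- make_permutations(ds, n_permutations, seed)
  }
  n_perm <- length(permutations)
  r <- length(repeat_seeds)
  original <- repeated_nested_cv(ds, cfg, grid, metric, n_outer, k_inner,
                                 repeat_seeds)
  perm_rncv <- numeric(n_perm)
  perm_ncv <- matrix(NA_real_, n_perm, r)
  perm_full <- if (keep_permuted) vector("list", n_perm)
  for (j in seq_len(n_perm)) {
    res <- repeated_nested_cv(permutations[[j]], cfg, grid, metric,
                              n_outer, k_inner, repeat_seeds)
    perm_rncv[j] <- res$mean_score
    perm_ncv[j, ] <- vapply(res$ncvs, `[[`, numeric(1), "mean_score")
    if (keep_permuted) perm_full[[j]] <- res
  }
  p_ncv_per_seed <- vapply(seq_len(r), function(s) {
    empirical_probability(original$ncvs[[s]]$mean_score, perm_ncv[, s])
  }, numeric(1))
  perm_labels <- do.call(rbind, lapply(permutations, function(p) {
    as.integer(p$labels)
  }))
  structure(
    list(metric = metric, original = original,
         p_rncv = empirical_probability(original$mean_score, perm_rncv),
         p_ncv_per_seed = p_ncv_per_seed,
         p_ncv_averaged = mean(p_ncv_per_seed),
         n_permutations = n_perm,
         permuted_rncv_scores = perm_rncv,
         permuted_ncv_scores = perm_ncv,
         permutation_labels = perm_labels,
         permuted_results = perm_full,
         repeat_seeds = as.integer(repeat_seeds),
         seed = as.integer(seed)),
    class = "rncv_permtest"
  )
}

#' @export
print.rncv_permtest <- function(x, ...) {
  cat(sprintf(
    paste0("<permutation test (%d permutations): %s = %.4f, ",
           "p_rncv = %.4f, p_ncv_averaged = %.4f>\n"),
    x$n_permutations, x$metric, x$original$mean_score, x$p_rncv,
    x$p_ncv_averaged))
  invisible(x)
}

#' Summarise the nCV-versus-rnCV comparison of a permutation test
#'
#' One row per dataset: the rnCV score with the spread of its component
#' nCV scores, and the two probabilities computed from the shared
#' permutations. The spread shows how strongly a single nCV depends on
#' the fold draw; the probability pair shows what aggregating repeats
#' before the comparison buys.
#'
#' @param result an `rncv_permtest`.
#' @return A one-row data frame with columns `score`, `score_min`,
#'   `score_max`, `score_sd`, `p_rncv`, `p_ncv_averaged`.
#' @export
compare_ncv_vs_rncv <- function(result) {
  stopifnot(inherits(result, "rncv_permtest"))
  o <- result$original
  data.frame(score = o$mean_score, score_min = o$score_min,
             score_max = o$score_max, score_sd = o$score_sd,
             p_rncv = result$p_rncv,
             p_ncv_averaged = result$p_ncv_averaged)
}
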