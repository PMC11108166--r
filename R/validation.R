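#' Stratified fold assignment
#'
#' Partitions the rows into `k` folds whose class proportions reflect the
#' full dataset: each class contributes `floor(n_c / k)` rows to every
#' fold, and the leftover rows are spread round-robin (with a seeded
#' starting fold) so that fold sizes differ by at most one. Every fold
#' contains at least one row of each class; if the minority class has
#' fewer than `k` rows the request is infeasible and an error of class
#' `rncv_stratification_error` is raised -- the caller must choose a
#' smaller `k` (no silent fallback).
#'
#' @param labels two-class label vector.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the within-class shuffles.
#' @return An object of class `rncv_fold_plan` with elements `k`,
#'   `assignments` (fold index per row) and `seed`.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  y <- as.character(labels)
  if (!is_count(k) || k < 2) {
    rncv_stop("k must be an integer >= 2", "rncv_config_error")
  }
  classes <- sort(unique(y))
  cnt <- table(factor(y, levels = classes))
  if (any(cnt < k)) {
    rncv_stop(sprintf(
      "stratification infeasible: class '%s' has %d rows but k = %d",
      names(cnt)[which.min(cnt)], min(cnt), k), "rncv_stratification_error")
  }
  assignments <- integer(length(y))
  with_seed(seed, {
    p <- sample.int(k, 1) - 1L  # rotating start for the leftover rows
    for (cl in classes) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      q <- length(idx) %/% k
      r <- length(idx) %% k
      folds <- c(rep(seq_len(k), q),
                 if (r > 0) ((p + seq_len(r) - 1L) %% k) + 1L)
      p <- (p + r) %% k
      assignments[idx] <- folds
    }
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed)),
            class = "rncv_fold_plan")
}

#' Hyperparameter grid for the SVM pipeline
#'
#' Declares candidate values per hyperparameter; the grid search tries
#' every combination. The default grid spans C in \{0.1, 1, 10\}, gamma
#' in \{0.1, scale, auto\}, all four kernels, and -- when feature
#' selection is in play -- 10 to 30 selected features in steps of 5
#' (36 or 180 combinations). Combinations are enumerated with the
#' first-declared parameter varying fastest; score ties resolve to the
#' earliest combination.
#'
#' @param C candidate regularisation values.
#' @param gamma candidate kernel widths (numbers, `"scale"`, `"auto"`).
#' @param kernel candidate kernels.
#' @param n_features_to_select candidate selected-feature counts, or
#'   `NULL` when feature selection is not tuned.
#' @return An object of class `rncv_grid`.
#' @export
svm_grid <- function(C = c(0.1, 1, 10),
                     gamma = c(0.1, "scale", "auto"),
                     kernel = c("linear", "rbf", "poly", "sigmoid"),
                     n_features_to_select = NULL) {
  if (length(C) == 0 || length(gamma) == 0 || length(kernel) == 0) {
    rncv_stop("grid lists must be non-empty", "rncv_config_error")
  }
  bad <- setdiff(kernel, names(KERNELS))
  if (length(bad) > 0) {
    rncv_stop(sprintf("unknown kernel '%s'", bad[1]), "rncv_config_error")
  }
  structure(list(C = as.numeric(C), gamma = as.character(gamma),
                 kernel = as.character(kernel),
                 n_features_to_select =
                   if (!is.null(n_features_to_select)) {
                     as.integer(n_features_to_select)
                   }),
            class = "rncv_grid")
}

#' Number of combinations in a grid
#' @param grid an [svm_grid()].
#' @return Integer combination count.
#' @export
grid_size <- function(grid) {
  n <- length(grid$C) * length(grid$gamma) * length(grid$kernel)
  if (!is.null(grid$n_features_to_select)) {
    n <- n * length(grid$n_features_to_select)
  }
  as.integer(n)
}

# Enumerate combinations in declaration order (first parameter fastest).
# `nf` is NA when feature selection is off, a constant when selection is
# on but its count is not tuned.
grid_combos <- function(grid, fs_on, nf_default) {
  if (fs_on && !is.null(grid$n_features_to_select)) {
    combos <- expand.grid(C = grid$C, gamma = grid$gamma,
                          kernel = grid$kernel,
                          nf = grid$n_features_to_select,
                          stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  } else {
    combos <- expand.grid(C = grid$C, gamma = grid$gamma,
                          kernel = grid$kernel,
                          stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    combos$nf <- if (fs_on) as.integer(nf_default) else NA_integer_
  }
  combos
}

# Score one set of hard predictions (integer codes) or ranking scores.
score_predictions <- function(metric, y_true_int, pred_int, scores,
                              pos_int) {
  if (metric == "auc") {
    pos <- y_true_int == pos_int
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) {
      rncv_stop("AUC undefined: one class absent from the test fold",
                "rncv_undefined_auc")
    }
    r <- rank(scores)
    return((sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  tp <- sum(y_true_int == pos_int & pred_int == pos_int)
  fp <- sum(y_true_int != pos_int & pred_int == pos_int)
  fn <- sum(y_true_int == pos_int & pred_int != pos_int)
  tn <- sum(y_true_int != pos_int & pred_int != pos_int)
  metric_score(metric, c(tp = tp, fp = fp, fn = fn, tn = tn))
}

# Inner grid search on integer labels. For every combination the full
# pipeline is evaluated on each inner fold; combinations that map to the
# same effective model (the linear kernel ignores gamma) share one fit.
grid_search_int <- function(X, y_int, lev, pos_int, combos, k_inner,
                            metric, oversample, seed) {
  k <- k_inner
  if (any(!is.na(combos$nf) & combos$nf > ncol(X))) {
    rncv_stop("n_features_to_select exceeds the feature count",
              "rncv_config_error")
  }
  plan <- stratified_folds(lev[y_int], k, derive_seed(seed, 1))
  m <- nrow(combos)
  fold_scores <- matrix(NA_real_, m, k)
  need_rank <- any(!is.na(combos$nf))
  for (f in seq_len(k)) {
    te <- plan$assignments == f
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y_int[!te]
    Xte <- X[te, , drop = FALSE]
    yte <- y_int[te]
    ranking <- if (need_rank) rank_features_mi(Xtr, lev[ytr]) else NULL
    std <- standardise_fit(Xtr)
    Xtr_s <- standardise_apply(std, Xtr)
    Xte_s <- standardise_apply(std, Xte)
    os <- if (oversample) oversample_indices(lev[ytr],
                                             derive_seed(seed, 2, f))
          else seq_along(ytr)
    yfit <- ytr[os]
    cache <- new.env(parent = emptyenv())
    for (ci in seq_len(m)) {
      kern <- combos$kernel[ci]
      gsp <- combos$gamma[ci]
      nf <- combos$nf[ci]
      key <- paste(kern, combos$C[ci],
                   if (kern == "linear") "" else gsp, nf, sep = "|")
      hit <- cache[[key]]
      if (!is.null(hit)) {
        fold_scores[ci, f] <- hit
        next
      }
      cols <- if (is.na(nf)) seq_len(ncol(X)) else ranking[seq_len(nf)]
      Xfit <- Xtr_s[os, cols, drop = FALSE]
      gamma <- resolve_gamma(gsp, Xfit)
      model <- svm_train(Xfit, yfit, kern, combos$C[ci], gamma)
      pr <- svm_decision(model, Xte_s[, cols, drop = FALSE])
      sc <- score_predictions(metric, yte, pr$class_int,
                              orient_scores(model, pr$dec, pos_int),
                              pos_int)
      cache[[key]] <- sc
      fold_scores[ci, f] <- sc
    }
  }
  mean_scores <- rowMeans(fold_scores)
  best <- which.max(mean_scores)  # ties: first declared combination
  list(best = list(C = combos$C[best], gamma = combos$gamma[best],
                   kernel = combos$kernel[best],
                   n_features_to_select =
                     if (is.na(combos$nf[best])) NULL
                     else combos$nf[best]),
       mean_scores = mean_scores, fold_scores = fold_scores)
}

#' Exhaustive grid search via inner stratified cross-validation
#'
#' Evaluates every hyperparameter combination with a stratified
#' `k_inner`-fold CV on the training partition, fitting the full pipeline
#' (selection, standardisation, oversampling, SVM) per inner fold, and
#' returns the combination with the highest mean score of the chosen
#' metric -- the same metric later used for evaluation. Ties resolve to
#' the first combination in declaration order.
#'
#' @param X_train,y_train the training partition.
#' @param grid an [svm_grid()].
#' @param k_inner inner fold count (default 5).
#' @param metric metric id used for selection.
#' @param cfg an [pipeline_config()]; its flags decide whether feature
#'   selection participates.
#' @param seed integer seed for folds and oversampling.
#' @param positive_class positive class; defaults to the training
#'   partition's minority class.
#' @return A list with `best_params` and `inner_scores` (a data frame of
#'   all combinations with their per-fold and mean scores).
#' @export
grid_search <- function(X_train, y_train, grid = svm_grid(), k_inner = 5,
                        metric = "mcc", cfg = pipeline_config(), seed = 1L,
                        positive_class = NULL) {
  check_metric(metric)
  lev <- sort(unique(as.character(y_train)))
  if (length(lev) != 2) {
    rncv_stop("training partition must contain exactly two classes",
              "rncv_degenerate_fold")
  }
  y_int <- match(as.character(y_train), lev)
  positive_class <- positive_class %||% minority_class(y_train)
  combos <- grid_combos(grid, cfg$use_feature_selection,
                        cfg$n_features_to_select)
  gs <- grid_search_int(as.matrix(X_train), y_int, lev,
                        match(positive_class, lev), combos, k_inner,
                        metric, cfg$oversample, seed)
  inner_scores <- cbind(combos, mean_score = gs$mean_scores,
                        as.data.frame(gs$fold_scores))
  names(inner_scores)[seq(ncol(combos) + 2, ncol(inner_scores))] <-
    paste0("fold", seq_len(k_inner))
  list(best_params = gs$best, inner_scores = inner_scores)
}

#' Nested cross-validation of the SVM pipeline
#'
#' The outer stratified `n_outer`-fold CV estimates generalisation
#' performance; within each outer training partition an inner stratified
#' `k_inner`-fold grid search picks the hyperparameters (skipped when
#' tuning is off, in which case the config defaults are used and, with
#' feature selection on, the default feature count). The winning pipeline
#' is refitted on the whole outer training partition and scored once on
#' the held-out fold; the nCV score is the mean over outer folds. The
#' positive class is the minority class of the full dataset.
#'
#' @param ds an [rncv_dataset].
#' @param cfg an [pipeline_config()].
#' @param grid an [svm_grid()]; `NULL` builds the default grid matching
#'   `cfg` (feature counts included only when selection is on).
#' @param metric metric id used for both tuning and evaluation.
#' @param n_outer outer folds (default 10).
#' @param k_inner inner folds (default 5).
#' @param seed integer seed; one seed governs all stochastic stages of
#'   the run (fold draws, oversampling).
#' @return An object of class `rncv_ncv`: fold scores, their mean,
#'   chosen parameters and confusion matrix per fold.
#' @export
nested_cv <- function(ds, cfg = pipeline_config(), grid = NULL,
                      metric = "mcc", n_outer = 10, k_inner = 5,
                      seed = 1L) {
  stopifnot(inherits(ds, "rncv_dataset"), inherits(cfg, "rncv_config"))
  check_metric(metric)
  lev <- levels(ds$labels)
  y_int <- as.integer(ds$labels)
  positive <- minority_class(ds$labels)
  pos_int <- match(positive, lev)
  X <- ds$features
  combos <- NULL
  if (cfg$use_hyperparameter_tuning) {
    if (is.null(grid)) {
      grid <- svm_grid(n_features_to_select =
                         if (cfg$use_feature_selection) {
                           seq(10L, 30L, by = 5L)
                         })
    }
    if (!cfg$use_feature_selection &&
        !is.null(grid$n_features_to_select)) {
      warning("feature selection is off; dropping n_features_to_select ",
              "from the grid")
      grid$n_features_to_select <- NULL
    }
    combos <- grid_combos(grid, cfg$use_feature_selection,
                          cfg$n_features_to_select)
  }
  plan <- stratified_folds(ds$labels, n_outer, derive_seed(seed, 1))
  fold_scores <- numeric(n_outer)
  chosen <- vector("list", n_outer)
  confusions <- vector("list", n_outer)
  for (i in seq_len(n_outer)) {
    te <- plan$assignments == i
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y_int[!te]
    Xte <- X[te, , drop = FALSE]
    yte <- y_int[te]
    if (!is.null(combos)) {
      gs <- grid_search_int(Xtr, ytr, lev, pos_int, combos, k_inner,
                            metric, cfg$oversample,
                            derive_seed(seed, 2, i))
      p <- gs$best
    } else {
      p <- list(C = cfg$C, gamma = as.character(cfg$gamma),
                kernel = cfg$kernel,
                n_features_to_select =
                  if (cfg$use_feature_selection) {
                    cfg$n_features_to_select
                  })
    }
    sel <- NULL
    if (cfg$use_feature_selection) {
      if (p$n_features_to_select > ncol(Xtr)) {
        rncv_stop("n_features_to_select exceeds the feature count",
                  "rncv_config_error")
      }
      ranking <- rank_features_mi(Xtr, lev[ytr])
      sel <- ranking[seq_len(p$n_features_to_select)]
    }
    fit <- fit_core(Xtr, ytr, sel, p$kernel, p$C, p$gamma,
                    cfg$oversample, derive_seed(seed, 3, i))
    pr <- predict_core(fit, Xte)
    fold_scores[i] <- score_predictions(
      metric, yte, pr$class_int,
      orient_scores(fit$model, pr$dec, pos_int), pos_int)
    tp <- sum(yte == pos_int & pr$class_int == pos_int)
    fp <- sum(yte != pos_int & pr$class_int == pos_int)
    fn <- sum(yte == pos_int & pr$class_int != pos_int)
    tn <- sum(yte != pos_int & pr$class_int != pos_int)
    confusions[[i]] <- new_confusion(tp, fp, fn, tn)
    chosen[[i]] <- p
  }
  structure(
    list(metric = metric, seed = as.integer(seed),
         n_outer = as.integer(n_outer), k_inner = as.integer(k_inner),
         fold_scores = fold_scores, mean_score = mean(fold_scores),
         chosen_params = chosen, confusions = confusions,
         positive_class = positive),
    class = "rncv_ncv"
  )
}

#' @export
print.rncv_ncv <- function(x, ...) {
  cat(sprintf("<nested CV: %s = %.4f over %d outer folds (seed %d)>\n",
              x$metric, x$mean_score, x$n_outer, x$seed))
  invisible(x)
}

#' Repeated nested cross-validation
#'
#' Runs one [nested_cv()] per repeat seed (different fold assignments)
#' and averages the repeat means; the spread across repeats (min, max,
#' sd) quantifies how much a single nCV depends on the draw of folds,
#' which grows as datasets shrink. The confusion matrices of all outer
#' folds of all repeats are averaged entry-wise.
#'
#' @inheritParams nested_cv
#' @param repeat_seeds integer vector of repeat seeds (default `1:5`).
#' @return An object of class `rncv_rncv` containing the per-repeat
#'   `rncv_ncv` objects; its `mean_score` is exactly the arithmetic mean
#'   of the repeat means.
#' @export
repeated_nested_cv <- function(ds, cfg = pipeline_config(), grid = NULL,
                               metric = "mcc", n_outer = 10, k_inner = 5,
                               repeat_seeds = 1:5) {
  if (length(repeat_seeds) < 1) {
    rncv_stop("repeat_seeds must be non-empty", "rncv_config_error")
  }
  ncvs <- lapply(repeat_seeds, function(s) {
    nested_cv(ds, cfg, grid, metric, n_outer, k_inner, seed = s)
  })
  means <- vapply(ncvs, `[[`, numeric(1), "mean_score")
  structure(
    list(metric = metric, repeat_seeds = as.integer(repeat_seeds),
         ncvs = ncvs, mean_score = mean(means),
         score_min = min(means), score_max = max(means),
         score_sd = if (length(means) > 1) stats::sd(means) else 0,
         confusion = average_confusions(
           unlist(lapply(ncvs, `[[`, "confusions"), recursive = FALSE))),
    class = "rncv_rncv"
  )
}

#' @export
print.rncv_rncv <- function(x, ...) {
  cat(sprintf(
    "<repeated nested CV: %s = %.4f (%d repeats, range %.4f..%.4f, sd %.4f)>\n",
    x$metric, x$mean_score, length(x$repeat_seeds), x$score_min,
    x$score_max, x$score_sd))
  invisible(x)
}

#' Single stratified train/test-split evaluation
#'
#' Splits the data once (stratified by class), fits the pipeline on the
#' training part -- with the inner-CV grid search when tuning is on --
#' and scores it once on the test part. Included as the baseline whose
#' seed-to-seed variance on small datasets motivates cross-validated
#' evaluation.
#'
#' @inheritParams nested_cv
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.8).
#' @return The test score, with attributes `n_train`, `n_test` and
#'   `chosen_params`.
#' @export
train_test_split_eval <- function(ds, train_fraction = 0.8,
                                  cfg = pipeline_config(), grid = NULL,
                                  metric = "mcc", k_inner = 5, seed = 1L) {
  stopifnot(inherits(ds, "rncv_dataset"))
  check_metric(metric)
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    rncv_stop("train_fraction must be in (0, 1)", "rncv_config_error")
  }
  lev <- levels(ds$labels)
  y_int <- as.integer(ds$labels)
  positive <- minority_class(ds$labels)
  pos_int <- match(positive, lev)
  tr <- logical(length(y_int))
  with_seed(derive_seed(seed, 1), {
    for (ci in 1:2) {
      idx <- which(y_int == ci)
      idx <- idx[sample.int(length(idx))]
      n_tr <- round(train_fraction * length(idx))
      tr[idx[seq_len(n_tr)]] <- TRUE
    }
  })
  if (length(unique(y_int[tr])) < 2 || length(unique(y_int[!tr])) < 2) {
    rncv_stop("a class is absent from the train or test partition",
              "rncv_partition_error")
  }
  Xtr <- ds$features[tr, , drop = FALSE]
  ytr <- y_int[tr]
  if (cfg$use_hyperparameter_tuning) {
    if (is.null(grid)) {
      grid <- svm_grid(n_features_to_select =
                         if (cfg$use_feature_selection) {
                           seq(10L, 30L, by = 5L)
                         })
    }
    combos <- grid_combos(grid, cfg$use_feature_selection,
                          cfg$n_features_to_select)
    gs <- grid_search_int(Xtr, ytr, lev, pos_int, combos, k_inner,
                          metric, cfg$oversample, derive_seed(seed, 2))
    p <- gs$best
  } else {
    p <- list(C = cfg$C, gamma = as.character(cfg$gamma),
              kernel = cfg$kernel,
              n_features_to_select =
                if (cfg$use_feature_selection) cfg$n_features_to_select)
  }
  sel <- NULL
  if (cfg$use_feature_selection) {
    if (p$n_features_to_select > ncol(Xtr)) {
      rncv_stop("n_features_to_select exceeds the feature count",
                "rncv_config_error")
    }
    ranking <- rank_features_mi(Xtr, lev[ytr])
    sel <- ranking[seq_len(p$n_features_to_select)]
  }
  fit <- fit_core(Xtr, ytr, sel, p$kernel, p$C, p$gamma, cfg$oversample,
                  derive_seed(seed, 3))
  pr <- predict_core(fit, ds$features[!tr, , drop = FALSE])
  score <- score_predictions(metric, y_int[!tr], pr$class_int,
                             orient_scores(fit$model, pr$dec, pos_int),
                             pos_int)
  structure(score, n_train = sum(tr), n_test = sum(!tr),
            chosen_params = p)
}

#' Ablation variants of a pipeline configuration
#'
#' The four configurations of the ablation study: both components on,
#' feature selection off, hyperparameter tuning off, and both off (the
#' last runs no inner CV at all -- config defaults throughout).
#'
#' @param base_cfg an [pipeline_config()] providing all other settings.
#' @return Named list of four `rncv_config` objects: `full`, `no_fs`,
#'   `no_hp`, `neither`.
#' @export
ablation_variants <- function(base_cfg = pipeline_config()) {
  variant <- function(fs, hp) {
    cfg <- base_cfg
    cfg$use_feature_selection <- fs
    cfg$use_hyperparameter_tuning <- hp
    cfg
  }
  list(full = variant(TRUE, TRUE), no_fs = variant(FALSE, TRUE),
       no_hp = variant(TRUE, FALSE), neither = variant(FALSE, FALSE))
}
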