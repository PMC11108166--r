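test_that("stratified folds reflect class proportions exactly", {
  y <- rep(c("min", "maj"), c(20, 30))
  plan <- stratified_folds(y, 10, seed = 3)
  for (f in 1:10) {
    in_fold <- plan$assignments == f
    expect_equal(sum(in_fold & y == "min"), 2)
    expect_equal(sum(in_fold & y == "maj"), 3)
  }
  expect_error(stratified_folds(rep(c("a", "b"), 1), 2, 1),
               class = "rncv_stratification_error")
})

test_that("stratified folds partition the rows with near-equal sizes", {
  set.seed(40)
  for (i in 1:15) {
    n <- sample(20:80, 1)
    y <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.35, 0.65))
    k <- sample(2:6, 1)
    if (min(table(y)) < k) next
    plan <- stratified_folds(y, k, seed = i)
    expect_setequal(unique(plan$assignments), seq_len(k))
    expect_length(plan$assignments, n)
    sizes <- tabulate(plan$assignments, k)
    expect_lte(diff(range(sizes)), 1)
    for (f in seq_len(k)) {
      expect_true(all(table(y[plan$assignments == f]) >= 1))
    }
  }
})

test_that("grid search evaluates every combination and honours ties", {
  ds <- generate_balanced_gaussian(40, seed = 6)
  cfg <- pipeline_config()
  gs <- grid_search(ds$features, ds$labels, svm_grid(), k_inner = 5,
                    metric = "mcc", cfg = cfg, seed = 2)
  expect_equal(nrow(gs$inner_scores), 36)  # 3 C x 3 gamma x 4 kernels
  expect_equal(gs$inner_scores$mean_score,
               rowMeans(gs$inner_scores[, paste0("fold", 1:5)]))
  best_row <- which.max(gs$inner_scores$mean_score)
  expect_equal(gs$best_params$C, gs$inner_scores$C[best_row])

  one <- svm_grid(C = 1, gamma = "auto", kernel = "linear")
  gs1 <- grid_search(ds$features, ds$labels, one, k_inner = 3,
                     metric = "acc", cfg = cfg, seed = 2)
  expect_equal(nrow(gs1$inner_scores), 1)
  expect_equal(gs1$best_params,
               list(C = 1, gamma = "auto", kernel = "linear",
                    n_features_to_select = NULL))
})

test_that("grid search fit count equals combinations x inner folds", {
  ds <- generate_balanced_gaussian(30, seed = 8)
  # a grid with no degenerate (gamma-free) duplicates
  grid <- svm_grid(C = c(0.5, 2), gamma = c(0.1, 0.3), kernel = "rbf")
  rncv:::reset_fit_count()
  grid_search(ds$features, ds$labels, grid, k_inner = 4, metric = "mcc",
              cfg = pipeline_config(), seed = 1)
  expect_equal(rncv:::get_fit_count(), grid_size(grid) * 4)
})

test_that("nested CV returns per-fold scores whose mean is the result", {
  ds <- generate_balanced_gaussian(40, seed = 10)
  cfg <- pipeline_config(use_hyperparameter_tuning = FALSE)
  res <- nested_cv(ds, cfg, metric = "mcc", n_outer = 5, seed = 4)
  expect_s3_class(res, "rncv_ncv")
  expect_length(res$fold_scores, 5)
  expect_identical(res$mean_score, mean(res$fold_scores))
  expect_length(res$confusions, 5)
  # outer-fold confusions jointly cover the whole dataset once
  expect_equal(sum(vapply(res$confusions, sum, 0)), 40)
})

test_that("nested CV achieves a perfect score on separable data", {
  ds <- separable_dataset(n = 30, d = 3)
  grid <- svm_grid(C = 1, gamma = "auto", kernel = "linear")
  res <- nested_cv(ds, pipeline_config(), grid, metric = "acc",
                   n_outer = 5, k_inner = 3, seed = 1)
  expect_equal(res$mean_score, 1.0)
})

test_that("ablating both components skips the inner CV entirely", {
  ds <- generate_balanced_gaussian(30, seed = 12)
  cfg <- ablation_variants(pipeline_config())$neither
  expect_false(cfg$use_feature_selection)
  expect_false(cfg$use_hyperparameter_tuning)
  rncv:::reset_fit_count()
  nested_cv(ds, cfg, metric = "mcc", n_outer = 6, seed = 2)
  expect_equal(rncv:::get_fit_count(), 6)  # outer refits only
  variants <- ablation_variants(pipeline_config())
  expect_named(variants, c("full", "no_fs", "no_hp", "neither"))
  expect_true(variants$full$use_feature_selection)
  expect_true(variants$full$use_hyperparameter_tuning)
  expect_false(variants$no_fs$use_feature_selection)
  expect_true(variants$no_fs$use_hyperparameter_tuning)
  expect_true(variants$no_hp$use_feature_selection)
  expect_false(variants$no_hp$use_hyperparameter_tuning)
})

test_that("repeated nested CV aggregates repeat means exactly", {
  ds <- generate_balanced_gaussian(30, seed = 14)
  cfg <- pipeline_config(use_hyperparameter_tuning = FALSE)
  rr <- repeated_nested_cv(ds, cfg, metric = "mcc", n_outer = 5,
                           repeat_seeds = 1:5)
  expect_length(rr$ncvs, 5)
  means <- vapply(rr$ncvs, `[[`, 0, "mean_score")
  expect_identical(rr$mean_score, mean(means))
  expect_identical(rr$score_min, min(means))
  expect_identical(rr$score_max, max(means))
  expect_equal(rr$score_sd, sd(means))

  one <- repeated_nested_cv(ds, cfg, metric = "mcc", n_outer = 5,
                            repeat_seeds = 3)
  expect_identical(one$mean_score, one$ncvs[[1]]$mean_score)
  expect_equal(one$score_sd, 0)
})

test_that("different repeat seeds change the folds, not the data", {
  ds <- generate_balanced_gaussian(30, seed = 16)
  cfg <- pipeline_config(use_hyperparameter_tuning = FALSE)
  a <- nested_cv(ds, cfg, metric = "acc", n_outer = 5, seed = 1)
  b <- nested_cv(ds, cfg, metric = "acc", n_outer = 5, seed = 2)
  a2 <- nested_cv(ds, cfg, metric = "acc", n_outer = 5, seed = 1)
  expect_identical(a$fold_scores, a2$fold_scores)
  expect_false(identical(a$fold_scores, b$fold_scores))
})

test_that("train/test split evaluation is stratified and seed-stable", {
  ds <- generate_balanced_gaussian(100, seed = 18)
  cfg <- pipeline_config(use_hyperparameter_tuning = FALSE)
  s <- train_test_split_eval(ds, 0.8, cfg, metric = "acc", seed = 1)
  expect_equal(attr(s, "n_train"), 80)
  expect_equal(attr(s, "n_test"), 20)
  s2 <- train_test_split_eval(ds, 0.8, cfg, metric = "acc", seed = 1)
  expect_identical(as.numeric(s), as.numeric(s2))

  scores <- vapply(1:5, function(sd) {
    as.numeric(train_test_split_eval(ds, 0.8, cfg, metric = "acc",
                                     seed = sd))
  }, 0)
  expect_gt(diff(range(scores)), 0)
  expect_error(train_test_split_eval(ds, 1.2, cfg),
               class = "rncv_config_error")
})
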