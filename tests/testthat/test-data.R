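test_that("generator splits classes floor(n/2) / remainder and is seed-stable", {
  for (n in c(2, 3, 25, 45, 50, 51)) {
    ds <- generate_balanced_gaussian(n, seed = 11)
    cnt <- table(ds$labels)
    expect_equal(unname(cnt[["class1"]]), n %/% 2)
    expect_equal(unname(cnt[["class2"]]), n - n %/% 2)
    expect_equal(nrow(ds$features), n)
  }
  a <- generate_balanced_gaussian(50, seed = 7)
  b <- generate_balanced_gaussian(50, seed = 7)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$features,
                         generate_balanced_gaussian(50, seed = 8)$features))
})

test_that("generator draws from the declared class distributions", {
  # law-of-large-numbers check on a single large draw
  ds <- generate_balanced_gaussian(100000, n_features = 1,
                                   class2_mean = 0.2, seed = 3)
  m2 <- mean(ds$features[ds$labels == "class2", 1])
  m1 <- mean(ds$features[ds$labels == "class1", 1])
  expect_lt(abs(m2 - 0.2), 0.01)
  expect_lt(abs(m1 - 0), 0.01)
})

test_that("generator rejects invalid specifications", {
  expect_error(generate_balanced_gaussian(1), class = "rncv_invalid_spec")
  expect_error(generate_balanced_gaussian(50, stddev = 0),
               class = "rncv_invalid_spec")
  expect_error(generate_balanced_gaussian(50, stddev = -1),
               class = "rncv_invalid_spec")
})

test_that("ensembles are sized, reproducible and consistent with single draws", {
  sizes <- c(25, 30, 40, 45, 50, 90, 130, 170, 210, 250, 290, 330)
  ens <- generate_ensemble(sizes, 2, seed = 5)
  expect_length(ens, 24)
  expect_equal(vapply(ens[1:2], function(d) nrow(d$features), 0),
               c(gaussian_n25_r1 = 25, gaussian_n25_r2 = 25))

  one <- generate_ensemble(50, 1, seed = 9)
  direct <- generate_balanced_gaussian(50,
                                       seed = rncv:::derive_seed(9, 1, 1))
  expect_identical(one[[1]]$features, direct$features)
  expect_identical(one[[1]]$labels, direct$labels)

  again <- generate_ensemble(sizes, 2, seed = 5)
  for (i in seq_along(ens)) {
    expect_identical(ens[[i]]$features, again[[i]]$features)
  }
})

test_that("CSV round-trip preserves features, labels and kinds", {
  path <- withr::local_tempfile(fileext = ".csv")
  ds <- generate_balanced_gaussian(20, n_features = 3, seed = 2)
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path, "label",
                           column_kinds = read_dataset_schema(path))
  expect_equal(back$features, ds$features, tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  expect_equal(back$column_kinds, ds$column_kinds)
})

test_that("CSV loader validates labels and missing cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,label", "1,2,x", "3,4,y", "5,6,x", "7,8,y"), path)
  ds <- read_dataset_csv(path, "label")
  expect_equal(nrow(ds$features), 4)
  expect_equal(levels(ds$labels), c("x", "y"))

  writeLines(c("a,label", "1,x", "2,y", "3,z"), path)
  expect_error(read_dataset_csv(path, "label"), class = "rncv_label_arity")

  writeLines(c("a,b,label", "1,,x", "3,4,y", "5,6,x"), path)
  expect_error(read_dataset_csv(path, "label"), class = "rncv_parse_error",
               regexp = "row 1.*'b'")
})

test_that("one-hot encoding expands categorical columns correctly", {
  x <- cbind(num = c(1.5, 2.5, 3.5, 4.5), cat = c(1, 2, 3, 2))
  ds <- rncv_dataset(x, c("u", "v", "u", "v"),
                     column_kinds = c("numeric", "categorical"),
                     factor_levels = list(cat = c("a", "b", "c")))
  enc <- one_hot_encode(ds)
  expect_equal(ncol(enc$features), 4)
  expect_true(all(enc$column_kinds == "numeric"))
  ind <- enc$features[, c("cat=a", "cat=b", "cat=c")]
  expect_equal(rowSums(ind), rep(1, 4))
  expect_equal(enc$features[, "num"], x[, "num"])

  all_num <- generate_balanced_gaussian(10, seed = 1)
  expect_identical(one_hot_encode(all_num), all_num)
})

test_that("one-hot output width is the sum of category counts plus numerics", {
  # 14 categorical columns with known category counts, plus 2 numeric
  set.seed(31)
  cat_sizes <- sample(2:6, 14, replace = TRUE)
  n <- 40
  cols <- lapply(cat_sizes, function(k) sample.int(k, n, replace = TRUE))
  # ensure every category is observed
  for (j in seq_along(cols)) cols[[j]][seq_len(cat_sizes[j])] <-
    seq_len(cat_sizes[j])
  x <- cbind(do.call(cbind, cols), rnorm(n), rnorm(n))
  colnames(x) <- c(paste0("q", 1:14), "t1", "t2")
  ds <- rncv_dataset(x, rep(c("p", "q"), n / 2),
                     column_kinds = c(rep("categorical", 14),
                                      "numeric", "numeric"))
  enc <- one_hot_encode(ds)
  expect_equal(ncol(enc$features), sum(cat_sizes) + 2)
})

test_that("one-hot warns on a single-category column", {
  ds <- rncv_dataset(cbind(c = rep(1, 4)), c("a", "b", "a", "b"),
                     column_kinds = "categorical")
  expect_warning(enc <- one_hot_encode(ds), "single category")
  expect_equal(ncol(enc$features), 1)
  expect_equal(unname(enc$features[, 1]), rep(1, 4))
})

test_that("minority class follows counts, with sorted-first tie rule", {
  expect_equal(minority_class(rep(c("x", "y"), c(201, 314))), "x")
  expect_equal(minority_class(rep(c("b", "a"), c(25, 25))), "a")
  expect_error(minority_class(rep("a", 10)), class = "rncv_label_arity")
  # brute-force count oracle on random vectors
  set.seed(12)
  for (i in 1:25) {
    y <- sample(c("m", "w"), 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    counted <- names(which.min(table(y)))
    if (sum(y == "m") != sum(y == "w")) {
      expect_equal(minority_class(y), counted)
    }
  }
})

test_that("label permutation preserves the multiset and is uniform", {
  ds <- generate_balanced_gaussian(21, seed = 4)
  p <- permute_labels(ds, 99)
  expect_equal(table(p$labels), table(ds$labels))
  expect_identical(p$features, ds$features)
  expect_identical(permute_labels(ds, 99)$labels, p$labels)

  # n = 3 with labels (a, a, b): the 6 underlying permutations collapse
  # onto 3 arrangements, each with probability 1/3
  tiny <- rncv_dataset(matrix(1:3, 3, 1), c("a", "a", "b"))
  arr <- vapply(1:3000, function(s) {
    paste(as.character(permute_labels(tiny, s)$labels), collapse = "")
  }, "")
  freq <- table(arr) / length(arr)
  expect_length(freq, 3)
  expect_true(all(abs(freq - 1 / 3) < 0.04))
})

test_that("dataset validation rejects malformed inputs", {
  expect_error(rncv_dataset(matrix(1:4, 2), c("a", "b", "c")),
               class = "rncv_invalid_dataset")
  expect_error(rncv_dataset(matrix(1:4, 2), c("a", "a")),
               class = "rncv_label_arity")
  expect_error(rncv_dataset(matrix(c(1, NA, 3, 4), 2), c("a", "b")),
               class = "rncv_invalid_dataset")
})
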