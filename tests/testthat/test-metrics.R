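test_that("confusion counting matches exhaustive brute force", {
  cm <- confusion_matrix(c("+", "+", "-", "-"), c("+", "+", "-", "-"), "+")
  expect_equal(unclass(cm), c(tp = 2, fp = 0, fn = 0, tn = 2))
  cm <- confusion_matrix(c("+", "-"), c("+", "+"), "+")
  expect_equal(unclass(cm), c(tp = 1, fp = 1, fn = 0, tn = 0))

  set.seed(20)
  for (i in 1:30) {
    y <- sample(c("p", "n"), 6, replace = TRUE)
    p <- sample(c("p", "n"), 6, replace = TRUE)
    cm <- confusion_matrix(y, p, "p")
    brute <- c(tp = sum(y == "p" & p == "p"), fp = sum(y == "n" & p == "p"),
               fn = sum(y == "p" & p == "n"), tn = sum(y == "n" & p == "n"))
    expect_equal(unclass(cm), brute)
    expect_equal(sum(cm), 6)
  }
  expect_error(confusion_matrix(c("a", "b"), c("a",  "b", "b"), "a"),
               class = "rncv_invalid_input")
  expect_error(confusion_matrix(c("a", "b"), c("a", "c"), "a"),
               class = "rncv_invalid_input")
})

test_that("threshold metrics match their standard definitions", {
  expect_equal(metric_score("mcc", c(tp = 2, fp = 0, fn = 0, tn = 2)), 1)
  # all-negative prediction: zero-denominator convention gives 0
  expect_equal(metric_score("mcc", c(tp = 0, fp = 0, fn = 1, tn = 1)), 0)
  expect_equal(metric_score("precision", c(tp = 0, fp = 0, fn = 1, tn = 1)),
               0)
  expect_equal(metric_score("f1", c(tp = 0, fp = 0, fn = 2, tn = 2)), 0)

  set.seed(21)
  for (i in 1:40) {
    cm <- as.numeric(rmultinom(1, size = sample(4:30, 1), prob = rep(1, 4)))
    cm <- c(tp = cm[1], fp = cm[2], fn = cm[3], tn = cm[4])
    tot <- sum(cm)
    expect_equal(metric_score("acc", cm), (cm[["tp"]] + cm[["tn"]]) / tot)
    rec_p <- if (cm[["tp"]] + cm[["fn"]] > 0) {
      cm[["tp"]] / (cm[["tp"]] + cm[["fn"]])
    } else 0
    rec_n <- if (cm[["tn"]] + cm[["fp"]] > 0) {
      cm[["tn"]] / (cm[["tn"]] + cm[["fp"]])
    } else 0
    expect_equal(metric_score("ba", cm), (rec_p + rec_n) / 2)
  }
  expect_error(metric_score("acc", c(tp = 0, fp = 0, fn = 0, tn = 0)),
               class = "rncv_invalid_input")
  expect_error(metric_score("auc", c(tp = 1, fp = 0, fn = 0, tn = 1)),
               class = "rncv_config_error")
})

test_that("MCC equals the phi coefficient; kappa/MCC are 1 iff error-free", {
  for (total in c(4, 8)) {
    for (cm in enumerate_confusions(total)) {
      phi <- phi_from_confusion(cm[1], cm[2], cm[3], cm[4])
      if (!is.na(phi)) {
        expect_equal(metric_score("mcc", cm), phi, tolerance = 1e-12)
      }
      both_present <- (cm[["tp"]] + cm[["fn"]] > 0) &&
        (cm[["tn"]] + cm[["fp"]] > 0)
      if (both_present) {
        perfect <- cm[["fp"]] == 0 && cm[["fn"]] == 0
        expect_equal(metric_score("kappa", cm) == 1, perfect)
        expect_equal(metric_score("mcc", cm) == 1, perfect)
      }
    }
  }
})

test_that("AUC follows the Mann-Whitney pair-counting definition", {
  y <- c("p", "p", "n", "n")
  expect_equal(auc_score(y, c(4, 3, 2, 1), "p"), 1)
  expect_equal(auc_score(y, rep(1, 4), "p"), 0.5)
  set.seed(22)
  for (i in 1:30) {
    y <- rep(c("p", "n"), c(5, 5))
    s <- sample(1:4, 10, replace = TRUE)  # forces ties
    expect_equal(auc_score(y, s, "p"), auc_pair_counting(y, s, "p"))
  }
  expect_error(auc_score(rep("p", 4), 1:4, "p"),
               class = "rncv_undefined_auc")
})

test_that("normalisation maps correlation metrics onto [0, 1] bijectively", {
  expect_equal(normalise_score("mcc", 0), 0.5)
  expect_equal(normalise_score("mcc", 1), 1)
  expect_equal(normalise_score("kappa", -1), 0)
  expect_equal(normalise_score("acc", 0.7), 0.7)
  # monotone on a grid spanning each metric's range
  for (m in c("mcc", "kappa", "f1", "auc")) {
    lo <- if (m %in% c("mcc", "kappa")) -1 else 0
    v <- seq(lo, 1, length.out = 21)
    nv <- vapply(v, function(x) normalise_score(m, x), 0)
    expect_true(all(diff(nv) > 0))
    expect_true(all(nv >= 0 & nv <= 1))
  }
  expect_error(normalise_score("acc", 1.2), class = "rncv_range_error")
  expect_error(normalise_score("mcc", -1.2), class = "rncv_range_error")
})

test_that("confusion averaging is entry-wise and conserves total mass", {
  a <- confusion_matrix(c("p", "p", "n", "n"), c("p", "p", "n", "n"), "p")
  b <- confusion_matrix(c("p", "p", "n", "n"), c("n", "n", "p", "p"), "p")
  avg <- average_confusions(list(a, b))
  expect_equal(unclass(avg), c(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_equal(unclass(average_confusions(list(a))), unclass(a))
  expect_error(average_confusions(list()), class = "rncv_invalid_input")

  set.seed(23)
  cms <- lapply(1:7, function(i) {
    v <- as.numeric(rmultinom(1, 12, rep(1, 4)))
    rncv:::new_confusion(v[1], v[2], v[3], v[4])
  })
  expect_equal(sum(average_confusions(cms)),
               mean(vapply(cms, sum, 0)))
})
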