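# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# Phi coefficient: Pearson correlation of the 0/1 truth and prediction
# indicator vectors reconstructed from a confusion matrix. NA when either
# vector is constant.
phi_from_confusion <- function(tp, fp, fn, tn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  if (length(truth) < 2 || stats::sd(truth) == 0 ||
      stats::sd(pred) == 0) {
    return(NA_real_)
  }
  stats::cor(truth, pred)
}

# AUC by exhaustive pair counting with the tie-counts-half convention.
auc_pair_counting <- function(y_true, y_score, positive) {
  pos <- which(y_true == positive)
  neg <- which(y_true != positive)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      total <- total +
        if (y_score[i] > y_score[j]) 1
        else if (y_score[i] == y_score[j]) 0.5
        else 0
    }
  }
  total / (length(pos) * length(neg))
}

# All confusion matrices (tp, fp, fn, tn) with tp+fp+fn+tn == total.
enumerate_confusions <- function(total) {
  out <- list()
  for (tp in 0:total) {
    for (fp in 0:(total - tp)) {
      for (fn in 0:(total - tp - fp)) {
        out[[length(out) + 1]] <- c(tp = tp, fp = fp, fn = fn,
                                    tn = total - tp - fp - fn)
      }
    }
  }
  out
}

# Two well-separated Gaussian blobs: linearly separable toy data.
separable_dataset <- function(n = 30, d = 4, gap = 10, seed = 42) {
  with_seed_local <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  with_seed_local(seed, {
    n1 <- n %/% 2
    x <- rbind(matrix(rnorm(n1 * d), n1),
               matrix(rnorm((n - n1) * d, mean = gap), n - n1))
    rncv_dataset(x, rep(c("lo", "hi"), c(n1, n - n1)), name = "separable")
  })
}
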