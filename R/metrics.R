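# The eight evaluation metrics, computed from a 2x2 confusion matrix
# (all but AUC) or from continuous ranking scores (AUC). Entries are kept
# as reals so that averaged matrices with fractional counts score
# identically to integer ones.

METRIC_IDS <- c("acc", "ba", "precision", "recall", "f1", "mcc", "kappa",
                "auc")

check_metric <- function(metric) {
  if (!is.character(metric) || length(metric) != 1 ||
      !metric %in% METRIC_IDS) {
    rncv_stop(sprintf("metric must be one of: %s",
                      paste(METRIC_IDS, collapse = ", ")),
              "rncv_config_error")
  }
  metric
}

#' Confusion matrix of a binary prediction
#'
#' Counts true/false positives/negatives with respect to a declared
#' positive class. The remaining observed class is the negative class.
#'
#' @param y_true,y_pred equal-length vectors over the dataset's two
#'   classes.
#' @param positive_class the positive class code.
#' @return An object of class `rncv_confusion`: named numeric vector
#'   `(tp, fp, fn, tn)`.
#' @export
confusion_matrix <- function(y_true, y_pred, positive_class) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    rncv_stop("y_true and y_pred must have equal length",
              "rncv_invalid_input")
  }
  classes <- sort(unique(c(y_true, y_pred)))
  if (!positive_class %in% classes) classes <- c(classes, positive_class)
  if (length(classes) > 2) {
    rncv_stop("labels outside the dataset's two classes",
              "rncv_invalid_input")
  }
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  new_confusion(tp, fp, fn, tn)
}

new_confusion <- function(tp, fp, fn, tn) {
  structure(c(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "rncv_confusion")
}

#' @export
print.rncv_confusion <- function(x, ...) {
  m <- matrix(c(x[["tp"]], x[["fn"]], x[["fp"]], x[["tn"]]), 2, 2,
              dimnames = list(c("true +", "true -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' Score a confusion matrix with one of the threshold metrics
#'
#' Computes accuracy, balanced accuracy, precision, recall, F1, Matthews
#' correlation coefficient or Cohen's kappa from a confusion matrix.
#' Whenever a needed denominator is zero (e.g. MCC with an all-negative
#' prediction) the score is defined as 0, which keeps degenerate
#' classifiers at chance level and permutation-test scores well defined.
#'
#' @param metric one of `"acc"`, `"ba"`, `"precision"`, `"recall"`,
#'   `"f1"`, `"mcc"`, `"kappa"`.
#' @param cm an `rncv_confusion` (or numeric vector `tp, fp, fn, tn`).
#' @return The score: in `[0, 1]` for acc/ba/precision/recall/f1, in
#'   `[-1, 1]` for mcc/kappa.
#' @export
metric_score <- function(metric, cm) {
  check_metric(metric)
  if (metric == "auc") {
    rncv_stop("auc requires ranking scores; use auc_score()",
              "rncv_config_error")
  }
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  if (any(c(tp, fp, fn, tn) < 0)) {
    rncv_stop("confusion entries must be non-negative", "rncv_invalid_input")
  }
  total <- tp + fp + fn + tn
  if (total == 0) {
    rncv_stop("empty evaluation: confusion total is 0", "rncv_invalid_input")
  }
  switch(metric,
    acc = (tp + tn) / total,
    recall = safe_div(tp, tp + fn),
    precision = safe_div(tp, tp + fp),
    f1 = safe_div(2 * tp, 2 * tp + fp + fn),
    ba = (safe_div(tp, tp + fn) + safe_div(tn, tn + fp)) / 2,
    mcc = {
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    },
    kappa = {
      po <- (tp + tn) / total
      pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / total^2
      safe_div(po - pe, 1 - pe)
    }
  )
}

#' Area under the ROC curve from ranking scores
#'
#' Mann-Whitney formulation with mid-rank handling of ties: the
#' probability that a random positive outranks a random negative, ties
#' counting one half. All-equal scores therefore give 0.5.
#'
#' @param y_true label vector containing both classes.
#' @param y_score continuous scores, higher = more positive.
#' @param positive_class the positive class code.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(y_true, y_score, positive_class) {
  y_true <- as.character(y_true)
  if (length(y_true) != length(y_score)) {
    rncv_stop("y_true and y_score must have equal length",
              "rncv_invalid_input")
  }
  pos <- y_true == positive_class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    rncv_stop("AUC undefined: one class absent from y_true",
              "rncv_undefined_auc")
  }
  r <- rank(y_score)  # mid-ranks on ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normalise a metric value onto `[0, 1]`
#'
#' MCC and kappa live on `[-1, 1]`; mapping them through `(x + 1) / 2`
#' puts every metric on the same scale for cross-metric comparison plots
#' and tables. All other metrics are returned unchanged.
#'
#' @param metric a metric id.
#' @param value a score in the metric's natural range.
#' @return The normalised value in `[0, 1]`.
#' @export
normalise_score <- function(metric, value) {
  check_metric(metric)
  lo <- if (metric %in% c("mcc", "kappa")) -1 else 0
  if (!is.numeric(value) || any(value < lo - 1e-12) ||
      any(value > 1 + 1e-12)) {
    rncv_stop(sprintf("value outside the natural range [%g, 1] of %s",
                      lo, metric), "rncv_range_error")
  }
  if (metric %in% c("mcc", "kappa")) (value + 1) / 2 else value
}

#' Entry-wise average of confusion matrices
#'
#' Repeated evaluation produces one confusion matrix per outer fold and
#' repeat; their entry-wise arithmetic mean (fractional entries allowed)
#' summarises the error structure of the whole evaluation.
#'
#' @param cms non-empty list of `rncv_confusion` objects.
#' @return An `rncv_confusion` with averaged entries.
#' @export
average_confusions <- function(cms) {
  if (length(cms) == 0) {
    rncv_stop("cannot average an empty list of confusion matrices",
              "rncv_invalid_input")
  }
  m <- rowMeans(vapply(cms, function(cm) {
    c(cm[["tp"]], cm[["fp"]], cm[["fn"]], cm[["tn"]])
  }, numeric(4)))
  new_confusion(m[1], m[2], m[3], m[4])
}
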