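#' Pipeline configuration
#'
#' Settings for the modelling pipeline fitted inside every training
#' partition: mutual-information feature selection, standardisation,
#' random oversampling, then an SVM. The `C` / `gamma` / `kernel` values
#' here are the *defaults* used whenever hyperparameter tuning is off
#' (C = 1, gamma = "scale", rbf kernel); with tuning on they are
#' superseded by the grid search winner.
#'
#' @param use_feature_selection rank features by mutual information and
#'   keep the top `n_features_to_select` (default `FALSE`; the synthetic
#'   generator's features are exchangeable, so selection is off there).
#' @param use_hyperparameter_tuning run the inner-CV grid search
#'   (default `TRUE`).
#' @param n_features_to_select features kept when selection is on and
#'   tuning is off (default 10, the smallest grid value).
#' @param C SVM regularisation parameter (> 0).
#' @param gamma kernel width: a positive number, `"scale"`
#'   (1 / (n_features * variance of the matrix reaching the kernel)) or
#'   `"auto"` (1 / n_features).
#' @param kernel one of `"linear"`, `"rbf"`, `"poly"`, `"sigmoid"`.
#' @param oversample balance training partitions by random oversampling
#'   of the minority class (default `TRUE`; a no-op on balanced data).
#' @param seed integer seed governing the pipeline's stochastic stages.
#' @return An object of class `rncv_config`.
#' @export
pipeline_config <- function(use_feature_selection = FALSE,
                            use_hyperparameter_tuning = TRUE,
                            n_features_to_select = 10,
                            C = 1, gamma = "scale", kernel = "rbf",
                            oversample = TRUE, seed = 1L) {
  if (!kernel %in% names(KERNELS)) {
    rncv_stop(sprintf("kernel must be one of: %s",
                      paste(names(KERNELS), collapse = ", ")),
              "rncv_config_error")
  }
  if (!is.numeric(C) || C <= 0) {
    rncv_stop("C must be > 0", "rncv_config_error")
  }
  if (!is_count(n_features_to_select) || n_features_to_select < 1) {
    rncv_stop("n_features_to_select must be a positive integer",
              "rncv_config_error")
  }
  if (!is.character(gamma)) {
    if (!is.numeric(gamma) || gamma <= 0) {
      rncv_stop("gamma must be positive, 'scale' or 'auto'",
                "rncv_config_error")
    }
  } else if (!gamma %in% c("scale", "auto") &&
             is.na(suppressWarnings(as.numeric(gamma)))) {
    rncv_stop("gamma must be positive, 'scale' or 'auto'",
              "rncv_config_error")
  }
  structure(
    list(use_feature_selection = isTRUE(use_feature_selection),
         use_hyperparameter_tuning = isTRUE(use_hyperparameter_tuning),
         n_features_to_select = as.integer(n_features_to_select),
         C = C, gamma = gamma, kernel = kernel,
         oversample = isTRUE(oversample), seed = as.integer(seed)),
    class = "rncv_config"
  )
}

#' Rank features by mutual information with the label
#'
#' Plug-in mutual-information estimate on the contingency table of each
#' (discretised) feature against the label. Columns with more than
#' `max_bins` distinct values are discretised into `max_bins` quantile
#' bins; columns with few distinct values (integer-coded categories,
#' one-hot indicators) are used as-is. The estimator is deterministic;
#' ties are broken towards the lower column index.
#'
#' @param X_train numeric training matrix (>= 2 rows).
#' @param y_train labels for the training rows; both classes present.
#' @param max_bins discretisation bins for continuous columns (default 10).
#' @return Integer vector of all column indices, sorted by decreasing
#'   estimated mutual information.
#' @export
rank_features_mi <- function(X_train, y_train, max_bins = 10) {
  y <- as.character(y_train)
  if (length(unique(y)) < 2) {
    rncv_stop("feature ranking needs both classes in the training data",
              "rncv_degenerate_fold")
  }
  mi <- vapply(seq_len(ncol(X_train)), function(j) {
    mutual_information(discretise_column(X_train[, j], max_bins), y)
  }, numeric(1))
  order(-mi, seq_along(mi))
}

discretise_column <- function(x, max_bins) {
  u <- unique(x)
  if (length(u) <= max_bins) {
    return(match(x, sort(u)))
  }
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
                                                max_bins + 1)))
  if (length(br) < 2) {
    return(rep(1L, length(x)))
  }
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

mutual_information <- function(xd, y) {
  tab <- table(xd, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / outer(px, py)[keep]))
}

#' Fit / apply standardisation parameters
#'
#' Column-wise centring and scaling by the *training* mean and population
#' standard deviation (the statistics of the rows the model is allowed to
#' see). Zero-variance columns are centred only. Standardisation rather
#' than min-max normalisation is used because no outlier removal is
#' performed upstream.
#'
#' @param X_train numeric training matrix.
#' @return `standardise_fit`: a list with `center` and `scale` vectors.
#' @export
standardise_fit <- function(X_train) {
  ctr <- colMeans(X_train)
  v <- colMeans(X_train^2) - ctr^2
  scl <- sqrt(pmax(v, 0))
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' @rdname standardise_fit
#' @param params a fit from `standardise_fit`.
#' @param X matrix to transform with the frozen training statistics.
#' @return `standardise_apply`: the transformed matrix.
#' @export
standardise_apply <- function(params, X) {
  X <- sweep(X, 2, params$center)
  sweep(X, 2, params$scale, "/")
}

#' Random oversampling of the minority class
#'
#' Duplicates minority-class rows (sampled with replacement) until both
#' classes have equal counts; majority rows are untouched and balanced
#' input is returned unchanged. Only ever applied to training partitions.
#'
#' @param X feature matrix.
#' @param y labels (both classes present).
#' @param seed integer seed.
#' @return A list with elements `X` and `y`.
#' @export
random_oversample <- function(X, y, seed) {
  y_chr <- as.character(y)
  idx <- oversample_indices(y_chr, seed)
  list(X = X[idx, , drop = FALSE], y = y[idx])
}

oversample_indices <- function(y, seed) {
  cnt <- table(y)
  if (length(cnt) < 2) {
    rncv_stop("oversampling needs both classes", "rncv_degenerate_fold")
  }
  if (cnt[1] == cnt[2]) {
    return(seq_along(y))
  }
  minority <- names(cnt)[which.min(cnt)]
  deficit <- abs(cnt[[1]] - cnt[[2]])
  pool <- which(y == minority)
  extra <- with_seed(seed, pool[sample.int(length(pool), deficit,
                                           replace = TRUE)])
  c(seq_along(y), extra)
}

# Fast internal fit: selection indices are already resolved, labels are
# integer codes 1/2 against the dataset's sorted levels. Stage order is
# selection -> standardisation -> oversampling -> SVM; gamma is resolved
# against the matrix that actually reaches the kernel.
fit_core <- function(X, y_int, sel, kernel, cost, gamma_spec, oversample,
                     seed) {
  Xs <- if (is.null(sel)) X else X[, sel, drop = FALSE]
  std <- standardise_fit(Xs)
  Xt <- standardise_apply(std, Xs)
  yt <- y_int
  if (oversample) {
    idx <- oversample_indices(y_int, seed)
    if (length(idx) > length(y_int)) {
      Xt <- Xt[idx, , drop = FALSE]
      yt <- y_int[idx]
    }
  }
  gamma <- resolve_gamma(gamma_spec, Xt)
  model <- svm_train(Xt, yt, kernel, cost, gamma)
  list(model = model, sel = sel, std = std, kernel = kernel, cost = cost,
       gamma = gamma, gamma_spec = gamma_spec, n_input = ncol(X))
}

predict_core <- function(fit, X) {
  Xs <- if (is.null(fit$sel)) X else X[, fit$sel, drop = FALSE]
  svm_decision(fit$model, standardise_apply(fit$std, Xs))
}

#' Fit the full modelling pipeline on a training partition
#'
#' Applies, in order: mutual-information feature selection (optional),
#' standardisation, random oversampling (optional), and an SVM fit. Every
#' statistic involved -- the feature ranking, the standardisation
#' parameters, the oversampling draws -- is computed from the training
#' rows only, so the fitted object is invariant to whatever test data it
#' is later applied to.
#'
#' @param X_train numeric training matrix.
#' @param y_train training labels (both classes present).
#' @param cfg an [pipeline_config()] object.
#' @param positive_class positive class code; defaults to the minority
#'   class of `y_train`.
#' @return An object of class `rncv_pipeline` usable with [predict()].
#' @export
fit_pipeline <- function(X_train, y_train, cfg = pipeline_config(),
                         positive_class = NULL) {
  stopifnot(inherits(cfg, "rncv_config"))
  lev <- sort(unique(as.character(y_train)))
  if (length(lev) != 2) {
    rncv_stop("training partition must contain exactly two classes",
              "rncv_degenerate_fold")
  }
  y_int <- match(as.character(y_train), lev)
  positive_class <- positive_class %||% minority_class(y_train)
  sel <- NULL
  if (cfg$use_feature_selection) {
    if (cfg$n_features_to_select > ncol(X_train)) {
      rncv_stop("n_features_to_select exceeds the feature count",
                "rncv_config_error")
    }
    ranking <- rank_features_mi(X_train, y_train)
    sel <- ranking[seq_len(cfg$n_features_to_select)]
  }
  fit <- fit_core(X_train, y_int, sel, cfg$kernel, cfg$C, cfg$gamma,
                  cfg$oversample, cfg$seed)
  fit$levels <- lev
  fit$positive <- positive_class
  class(fit) <- "rncv_pipeline"
  fit
}

#' Predict with a fitted pipeline
#'
#' Test rows pass through the frozen feature selection and
#' standardisation; no oversampling happens at prediction time. Returns
#' hard labels together with the SVM's signed decision values oriented so
#' that larger means "more positive class" (the AUC ranking score).
#'
#' @param object an `rncv_pipeline`.
#' @param newdata matrix with the original (pre-selection) feature width.
#' @param ... unused.
#' @return A list with `labels` (factor) and `scores` (numeric).
#' @export
predict.rncv_pipeline <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_input) {
    rncv_stop(sprintf("newdata has %d columns, the pipeline was fitted on %d",
                      ncol(newdata), object$n_input), "rncv_invalid_input")
  }
  pr <- predict_core(object, newdata)
  pos_int <- match(object$positive, object$levels)
  list(labels = factor(object$levels[pr$class_int], levels = object$levels),
       scores = orient_scores(object$model, pr$dec, pos_int))
}
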