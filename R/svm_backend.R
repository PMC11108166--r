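# Thin binding to libsvm (via e1071) for dense binary C-classification.
#
# The evaluation machinery in this package refits the SVM hundreds of
# thousands of times on tiny matrices, where the cost of the public
# e1071::svm() wrapper (data-frame construction, NA handling, fitted
# values) dwarfs the actual optimisation. svm_train()/svm_decision()
# therefore marshal arguments for e1071's registered C routines directly,
# specialised to the one configuration used here: dense inputs, two
# classes, no scaling (standardisation happens upstream in the pipeline),
# no class weights, no probability model. When the symbols cannot be
# resolved, the public interface is used instead; both paths produce
# identical models and decision values.

KERNELS <- c(linear = 0L, poly = 1L, rbf = 2L, sigmoid = 3L)

EMPTY_ERR <- paste(rep(" ", 255), collapse = "")

# Resolve a gamma specification against the matrix that reaches the
# kernel: "scale" = 1 / (n_features * population variance of X),
# "auto" = 1 / n_features, otherwise a positive number.
resolve_gamma <- function(gamma, X) {
  if (is.character(gamma)) {
    if (gamma == "scale") {
      v <- mean((X - mean(X))^2)
      if (v == 0) v <- 1
      return(1 / (ncol(X) * v))
    }
    if (gamma == "auto") {
      return(1 / ncol(X))
    }
    num <- suppressWarnings(as.numeric(gamma))
    if (!is.na(num) && num > 0) {
      return(num)
    }
    rncv_stop(sprintf("invalid gamma specification '%s'", gamma),
              "rncv_config_error")
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma <= 0) {
    rncv_stop("gamma must be a positive number, 'scale' or 'auto'",
              "rncv_config_error")
  }
  gamma
}

# Train a binary C-SVC. `y_int` holds class codes 1/2; both must occur.
# Returns an opaque model list consumed by svm_decision().
svm_train <- function(X, y_int, kernel, cost, gamma, degree = 3, coef0 = 0) {
  .rncv$fit_count <- .rncv$fit_count + 1L
  kid <- KERNELS[[kernel]]
  if (is.null(kid)) {
    rncv_stop(sprintf("unknown kernel '%s'", kernel), "rncv_config_error")
  }
  if (length(unique(y_int)) < 2) {
    rncv_stop("training partition contains a single class",
              "rncv_degenerate_fold")
  }
  if (!is.null(.rncv$train_sym)) {
    nr <- nrow(X)
    cret <- .C(.rncv$train_sym, as.double(t(X)), as.integer(nr),
      as.integer(ncol(X)), as.double(y_int), integer(1), integer(1),
      0L,                                   # type: C-classification
      kid, as.integer(degree), as.double(gamma),
      as.double(coef0), as.double(cost), 0.5,
      integer(0), double(0), 0L,            # no class weights
      40, 0.001, 0.1,                       # cachesize, tolerance, epsilon
      1L, 0L, 0L, 0L,                       # shrinking, cross, sparse, prob
      nclasses = integer(1), nr = integer(1), index = integer(nr),
      labels = integer(2), nSV = integer(2), rho = double(1),
      coefs = double(nr), sigma = double(1), probA = double(1),
      probB = double(1), cresults = double(0), ctotal1 = double(1),
      ctotal2 = double(1), error = EMPTY_ERR)
    if (cret$error != EMPTY_ERR) {
      rncv_stop(paste0("libsvm: ", cret$error), "rncv_svm_error")
    }
    idx <- cret$index[seq_len(cret$nr)]
    return(list(SV = X[idx, , drop = FALSE],
                coefs = cret$coefs[seq_len(cret$nr)], rho = cret$rho,
                labels = cret$labels, nSV = cret$nSV, tot_nsv = cret$nr,
                kernel = kid, degree = degree, gamma = gamma, coef0 = coef0))
  }
  # fallback: public interface, stripped of its NA / fitted-value overhead
  fit <- e1071::svm(X, factor(y_int, levels = c(1, 2)),
                    type = "C-classification",
                    kernel = c("linear", "polynomial", "radial",
                               "sigmoid")[kid + 1L],
                    degree = degree, gamma = gamma, coef0 = coef0,
                    cost = cost, scale = FALSE, fitted = FALSE,
                    na.action = function(object, ...) object)
  list(e1071 = fit, labels = fit$labels, kernel = kid)
}

# Predict class codes (1/2) and signed decision values for new rows.
# The decision value is positive for the class whose code is labels[1]
# (the class of the first training row, as in libsvm).
svm_decision <- function(model, X) {
  if (!is.null(model$e1071)) {
    pr <- predict(model$e1071, X, decision.values = TRUE)
    return(list(class_int = as.integer(as.character(pr)),
                dec = as.numeric(attr(pr, "decision.values"))))
  }
  nt <- nrow(X)
  r <- .C(.rncv$pred_sym, 1L, 0L, as.double(t(model$SV)),
    as.integer(model$tot_nsv), as.integer(ncol(model$SV)), integer(1),
    integer(1), as.double(model$coefs), as.double(model$rho), 0L,
    as.double(0), as.double(0), 2L, as.integer(model$tot_nsv),
    as.integer(model$labels), as.integer(model$nSV), 0L, 0L,
    as.integer(model$kernel), as.integer(model$degree),
    as.double(model$gamma), as.double(model$coef0), as.double(t(X)),
    as.integer(nt), integer(1), integer(1), 0L,
    ret = double(nt), dec = double(nt), prob = double(nt * 2))
  list(class_int = as.integer(r$ret), dec = r$dec)
}

# Orient decision values so that larger means "more like the positive
# class" (code `pos_int`); used as the AUC ranking score.
orient_scores <- function(model, dec, pos_int) {
  if (model$labels[1] == pos_int) dec else -dec
}
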