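# Package-level state: resolved native symbols for the fast SVM path and
# a fit counter used by the test suite's counting oracles.
.rncv <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .rncv$fit_count <- 0L
  .rncv$train_sym <- NULL
  .rncv$pred_sym <- NULL
  # libsvm entry points registered by e1071; if resolution fails (e.g. a
  # build without registered routines) the backend falls back to the
  # public e1071::svm() interface, which is exact but slower.
  ok <- requireNamespace("e1071", quietly = TRUE)
  if (ok) {
    syms <- tryCatch(
      list(
        train = getNativeSymbolInfo("svmtrain", "e1071"),
        pred  = getNativeSymbolInfo("svmpredict", "e1071")
      ),
      error = function(e) NULL
    )
    if (!is.null(syms)) {
      .rncv$train_sym <- syms$train
      .rncv$pred_sym <- syms$pred
    }
  }
  invisible()
}

reset_fit_count <- function() .rncv$fit_count <- 0L
get_fit_count <- function() .rncv$fit_count
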