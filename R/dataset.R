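#' Binary-classification dataset container
#'
#' Bundles a numeric feature matrix with a two-class label vector and
#' per-column kind tags. Categorical columns are stored as 1-based integer
#' category codes; the original category labels are kept in
#' `factor_levels` so that [one_hot_encode()] can name its indicator
#' columns. All evaluation functions in the package operate on this class.
#'
#' @param features numeric matrix, rows = observations.
#' @param labels vector (or factor) with exactly two distinct values.
#' @param column_kinds character vector, one of `"numeric"` /
#'   `"categorical"` per column. Defaults to all numeric.
#' @param name free-text identifier carried through result objects.
#' @param seed integer seed the dataset was generated from, or `NULL`.
#' @param factor_levels named list mapping categorical column names to
#'   their category labels (in code order).
#' @return An object of class `rncv_dataset`.
#' @export
rncv_dataset <- function(features, labels, column_kinds = NULL,
                         name = "dataset", seed = NULL,
                         factor_levels = list()) {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  if (nrow(features) != length(labels)) {
    rncv_stop("row count of features must equal length of labels",
              "rncv_invalid_dataset")
  }
  if (anyNA(features) || anyNA(labels)) {
    rncv_stop("missing values are not supported; remove or recode them",
              "rncv_invalid_dataset")
  }
  uv <- sort(unique(as.character(labels)))
  if (length(uv) != 2) {
    rncv_stop(sprintf("labels must take exactly 2 distinct values, found %d",
                      length(uv)), "rncv_label_arity")
  }
  labels <- factor(as.character(labels), levels = uv)
  column_kinds <- column_kinds %||% rep("numeric", ncol(features))
  if (length(column_kinds) != ncol(features) ||
      !all(column_kinds %in% c("numeric", "categorical"))) {
    rncv_stop("column_kinds must tag every column 'numeric' or 'categorical'",
              "rncv_invalid_dataset")
  }
  structure(
    list(features = features, labels = labels,
         column_kinds = column_kinds, name = name, seed = seed,
         factor_levels = factor_levels),
    class = "rncv_dataset"
  )
}

#' @export
print.rncv_dataset <- function(x, ...) {
  cnt <- table(x$labels)
  cat(sprintf("<rncv_dataset '%s': %d x %d, classes %s (%s)>\n",
              x$name, nrow(x$features), ncol(x$features),
              paste(names(cnt), collapse = ":"),
              paste(cnt, collapse = ":")))
  invisible(x)
}

#' Generate a balanced two-class Gaussian dataset
#'
#' Emulates a simple study design for predictable synthetic data: class 1
#' receives `floor(n_points / 2)` observations whose features are drawn
#' i.i.d. from N(`class1_mean`, `stddev`^2), class 2 the remaining
#' observations from N(`class2_mean`, `stddev`^2), after which the row
#' order is shuffled. With the default mean shift of 0.2 the classes
#' overlap heavily, so a classifier can beat chance only modestly --
#' exactly the regime where scores alone are unreliable and a permutation
#' test is informative.
#'
#' @param n_points total number of observations (>= 2).
#' @param n_features number of features (default 10).
#' @param class1_mean,class2_mean per-class feature means (defaults 0, 0.2).
#' @param stddev common feature standard deviation (> 0).
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return An [rncv_dataset] with labels `"class1"` / `"class2"`.
#' @examples
#' ds <- generate_balanced_gaussian(50, seed = 1)
#' table(ds$labels)
#' @export
generate_balanced_gaussian <- function(n_points, n_features = 10,
                                       class1_mean = 0, class2_mean = 0.2,
                                       stddev = 1, seed = 1L) {
  if (!is_count(n_points) || n_points < 2) {
    rncv_stop("n_points must be an integer >= 2", "rncv_invalid_spec")
  }
  if (!is_count(n_features) || n_features < 1) {
    rncv_stop("n_features must be a positive integer", "rncv_invalid_spec")
  }
  if (!is.numeric(stddev) || stddev <= 0) {
    rncv_stop("stddev must be > 0", "rncv_invalid_spec")
  }
  n1 <- n_points %/% 2
  n2 <- n_points - n1
  with_seed(seed, {
    x1 <- matrix(stats::rnorm(n1 * n_features, class1_mean, stddev), n1)
    x2 <- matrix(stats::rnorm(n2 * n_features, class2_mean, stddev), n2)
    ord <- sample.int(n_points)
    features <- rbind(x1, x2)[ord, , drop = FALSE]
    labels <- rep(c("class1", "class2"), c(n1, n2))[ord]
    rncv_dataset(features, labels,
                 name = sprintf("gaussian_n%d_seed%d", n_points, seed),
                 seed = seed)
  })
}

#' Generate an ensemble of synthetic datasets
#'
#' Produces `count_per_size` independent datasets for every entry of
#' `sizes`, with child seeds derived deterministically from `seed` so the
#' whole ensemble is reproducible from one integer.
#'
#' @param sizes integer vector of dataset sizes.
#' @param count_per_size replicates per size (>= 1).
#' @param seed master seed.
#' @inheritParams generate_balanced_gaussian
#' @return A list of [rncv_dataset] objects, sizes varying slowest.
#' @export
generate_ensemble <- function(sizes, count_per_size, n_features = 10,
                              class1_mean = 0, class2_mean = 0.2,
                              stddev = 1, seed = 1L) {
  if (length(sizes) == 0) {
    rncv_stop("sizes must be non-empty", "rncv_invalid_spec")
  }
  if (!is_count(count_per_size) || count_per_size < 1) {
    rncv_stop("count_per_size must be >= 1", "rncv_invalid_spec")
  }
  out <- vector("list", length(sizes) * count_per_size)
  pos <- 0L
  for (si in seq_along(sizes)) {
    for (ri in seq_len(count_per_size)) {
      pos <- pos + 1L
      out[[pos]] <- generate_balanced_gaussian(
        sizes[si], n_features, class1_mean, class2_mean, stddev,
        seed = derive_seed(seed, si, ri)
      )
      out[[pos]]$name <- sprintf("gaussian_n%d_r%d", sizes[si], ri)
    }
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Load a tabular dataset from a delimited text file
#'
#' Reads a header-bearing delimited file, splits off the label column and
#' validates that it carries exactly two values. Character columns (and
#' any column tagged `"categorical"` in `column_kinds`) are recoded to
#' integer category codes with their labels retained for one-hot
#' encoding. Missing cells are rejected with the offending position named.
#'
#' @param path file path.
#' @param label_column name of the label column.
#' @param column_kinds optional named character vector tagging feature
#'   columns `"numeric"` / `"categorical"`; untagged columns default by
#'   their parsed type.
#' @param sep field delimiter (default comma).
#' @return An [rncv_dataset].
#' @export
read_dataset_csv <- function(path, label_column, column_kinds = NULL,
                             sep = ",") {
  if (!file.exists(path)) {
    rncv_stop(sprintf("file not found: %s", path), "rncv_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!label_column %in% names(df)) {
    rncv_stop(sprintf("label column '%s' not present", label_column),
              "rncv_io_error")
  }
  nas <- which(is.na(df), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    rncv_stop(sprintf("missing value at row %d, column '%s'",
                      nas[1, 1], names(df)[nas[1, 2]]), "rncv_parse_error")
  }
  labels <- as.character(df[[label_column]])
  if (length(unique(labels)) != 2) {
    rncv_stop(sprintf("label column '%s' has %d distinct values, need 2",
                      label_column, length(unique(labels))),
              "rncv_label_arity")
  }
  feat_df <- df[setdiff(names(df), label_column)]
  kinds <- vapply(feat_df, function(col) {
    if (is.numeric(col)) "numeric" else "categorical"
  }, "")
  if (!is.null(column_kinds)) {
    bad <- setdiff(names(column_kinds), names(feat_df))
    if (length(bad) > 0) {
      rncv_stop(sprintf("column_kinds names unknown column '%s'", bad[1]),
                "rncv_io_error")
    }
    kinds[names(column_kinds)] <- column_kinds
  }
  factor_levels <- list()
  features <- matrix(0, nrow(feat_df), ncol(feat_df),
                     dimnames = list(NULL, names(feat_df)))
  for (j in seq_along(feat_df)) {
    col <- feat_df[[j]]
    if (kinds[j] == "categorical") {
      lev <- sort(unique(as.character(col)))
      factor_levels[[names(feat_df)[j]]] <- lev
      features[, j] <- match(as.character(col), lev)
    } else {
      if (!is.numeric(col)) {
        rncv_stop(sprintf("column '%s' declared numeric but is not",
                          names(feat_df)[j]), "rncv_parse_error")
      }
      features[, j] <- col
    }
  }
  rncv_dataset(features, labels, unname(kinds),
               name = basename(path), factor_levels = factor_levels)
}

#' Write a dataset to a delimited text file with a schema sidecar
#'
#' The features and label are written as CSV; a plain-text sidecar
#' (`<path>.schema`) records each feature column's kind so that
#' [read_dataset_csv()] round-trips the object.
#'
#' @param ds an [rncv_dataset].
#' @param path output file path.
#' @param label_column name for the label column (default `"label"`).
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path, label_column = "label") {
  stopifnot(inherits(ds, "rncv_dataset"))
  df <- as.data.frame(ds$features)
  for (nm in names(ds$factor_levels)) {
    df[[nm]] <- ds$factor_levels[[nm]][df[[nm]]]
  }
  df[[label_column]] <- as.character(ds$labels)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  schema <- paste(colnames(ds$features), ds$column_kinds, sep = "\t")
  writeLines(schema, paste0(path, ".schema"))
  invisible(path)
}

#' Read the schema sidecar written by [write_dataset_csv()]
#' @param path the CSV path (the sidecar is `<path>.schema`).
#' @return named character vector of column kinds.
#' @export
read_dataset_schema <- function(path) {
  lines <- readLines(paste0(path, ".schema"))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(vapply(parts, `[[`, "", 2), vapply(parts, `[[`, "", 1))
}

#' One-hot encode categorical columns
#'
#' Replaces every categorical column by one 0/1 indicator column per
#' observed category (named `column=category`); numeric columns pass
#' through unchanged. Applied once to the whole dataset before any
#' resampling, so fold contents never change the encoding. A categorical
#' column with a single observed category yields one constant indicator
#' and a warning.
#'
#' @param ds an [rncv_dataset].
#' @return An [rncv_dataset] whose columns are all numeric.
#' @export
one_hot_encode <- function(ds) {
  stopifnot(inherits(ds, "rncv_dataset"))
  if (!any(ds$column_kinds == "categorical")) {
    return(ds)
  }
  blocks <- vector("list", ncol(ds$features))
  for (j in seq_len(ncol(ds$features))) {
    nm <- colnames(ds$features)[j]
    if (ds$column_kinds[j] == "numeric") {
      blocks[[j]] <- ds$features[, j, drop = FALSE]
    } else {
      lev <- ds$factor_levels[[nm]] %||%
        as.character(sort(unique(ds$features[, j])))
      codes <- if (is.null(ds$factor_levels[[nm]])) {
        match(as.character(ds$features[, j]), lev)
      } else {
        ds$features[, j]
      }
      if (length(lev) == 1) {
        warning(sprintf("categorical column '%s' has a single category", nm))
      }
      ind <- matrix(0, nrow(ds$features), length(lev),
                    dimnames = list(NULL, paste0(nm, "=", lev)))
      ind[cbind(seq_len(nrow(ind)), codes)] <- 1
      blocks[[j]] <- ind
    }
  }
  features <- do.call(cbind, blocks)
  rncv_dataset(features, ds$labels, rep("numeric", ncol(features)),
               name = ds$name, seed = ds$seed)
}

#' Minority class of a two-class label vector
#'
#' The minority class of the *full* dataset is used as the positive class
#' throughout, which keeps asymmetric metrics (precision, recall, F1)
#' comparable across evaluations. An exact tie is resolved to the class
#' that sorts first, which is deterministic and immaterial for symmetric
#' metrics on balanced data.
#'
#' @param labels factor or vector with exactly two distinct values.
#' @return The minority class code (character).
#' @export
minority_class <- function(labels) {
  uv <- sort(unique(as.character(labels)))
  if (length(uv) != 2) {
    rncv_stop(sprintf("need exactly 2 classes, found %d", length(uv)),
              "rncv_label_arity")
  }
  cnt <- table(factor(as.character(labels), levels = uv))
  uv[which.min(cnt)]  # ties: first in sorted order
}

#' Randomly permute a dataset's labels
#'
#' Draws a uniformly random permutation of the label vector over the
#' whole dataset (before any CV split), breaking the feature-label link
#' while preserving the class counts exactly. This is the null-model
#' operation underlying [permutation_test()].
#'
#' @param ds an [rncv_dataset].
#' @param seed integer seed.
#' @return An [rncv_dataset] with permuted labels and untouched features.
#' @export
permute_labels <- function(ds, seed) {
  stopifnot(inherits(ds, "rncv_dataset"))
  out <- ds
  out$labels <- with_seed(seed, ds$labels[sample.int(length(ds$labels))])
  out$name <- paste0(ds$name, "_perm")
  out
}
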