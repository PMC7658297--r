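#' Construct a feature matrix
#'
#' Container for a samples-by-features numeric matrix with unique named
#' columns, sample ids as row names, and an optional aligned 0/1 label
#' vector (1 = positive class).
#'
#' @param x Numeric matrix with row names (sample ids) and unique column
#'   names (feature names).
#' @param labels Optional integer 0/1 vector, one per row.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(x, labels = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature values must be numeric", call. = FALSE)
  if (is.null(colnames(x)) && ncol(x) > 0) {
    stop("feature columns must be named", call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("feature names must be unique", call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(x)) {
      stop("label count (", length(labels), ") != sample count (", nrow(x), ")",
           call. = FALSE)
    }
    if (any(is.na(labels)) || any(!labels %in% c(0L, 1L))) {
      stop("labels must be 0 or 1 with no NA", call. = FALSE)
    }
  }
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features%s\n",
              nrow(x$x), ncol(x$x),
              if (is.null(x$labels)) " (unlabeled)"
              else sprintf(" (%d pos / %d neg)",
                           sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

is_labeled <- function(fm) !is.null(fm$labels)

require_labels <- function(fm) {
  if (!is_labeled(fm)) stop("a labeled feature matrix is required", call. = FALSE)
  fm
}

#' Subset a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param samples Optional row index/ids.
#' @param features Optional feature names (or column indices); unknown names
#'   are an error.
#' @return A `feature_matrix`.
#' @export
fm_subset <- function(fm, samples = NULL, features = NULL) {
  x <- fm$x
  labels <- fm$labels
  if (!is.null(features)) {
    if (is.character(features)) {
      missing <- setdiff(features, colnames(x))
      if (length(missing)) {
        stop("unknown feature name(s): ",
             paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
      }
    }
    x <- x[, features, drop = FALSE]
  }
  if (!is.null(samples)) {
    x <- x[samples, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[samples]
  }
  feature_matrix(x, labels)
}

#' Write a feature matrix to CSV
#'
#' Layout: first column `sample_id`, then one named column per feature, and
#' (when labeled) a final `label` column holding 1/0. Header row mandatory,
#' UTF-8. [read_feature_csv()] inverts this exactly, including column order.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(sample_id = rownames(fm$x), fm$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (is_labeled(fm)) df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV path as written by [write_feature_csv()].
#' @param labeled `NA` (default) auto-detects a trailing `label` column;
#'   `TRUE` requires it (error if absent); `FALSE` ignores it as a feature.
#' @return A `feature_matrix`.
#' @export
read_feature_csv <- function(path, labeled = NA) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (ncol(df) < 1L || names(df)[1] != "sample_id") {
    stop("feature CSV must start with a 'sample_id' column: ", path,
         call. = FALSE)
  }
  has_label <- ncol(df) >= 2L && names(df)[ncol(df)] == "label"
  if (isTRUE(labeled) && !has_label) {
    stop("feature CSV has no 'label' column but labels were required: ", path,
         call. = FALSE)
  }
  use_label <- has_label && !isFALSE(labeled)
  labels <- if (use_label) df[[ncol(df)]] else NULL
  feat_cols <- setdiff(seq_along(df), c(1L, if (use_label) ncol(df)))
  # a zero-row CSV reads every column as logical; that is still numeric-safe
  col_ok <- function(col) is.numeric(col) || (is.logical(col) && all(is.na(col)))
  x <- as.matrix(df[, feat_cols, drop = FALSE])
  if (length(feat_cols) && !all(vapply(df[feat_cols], col_ok, logical(1)))) {
    bad <- which(!vapply(df[feat_cols], col_ok, logical(1)))[1]
    col <- feat_cols[bad]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
    stop("non-numeric feature value at row ", row, ", column '",
         names(df)[col], "' of ", path, call. = FALSE)
  }
  storage.mode(x) <- "double"
  rownames(x) <- as.character(df$sample_id)
  feature_matrix(x, labels)
}
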