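#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two equal-length numeric vectors.
#' Returns 0 with a warning when either vector has zero variance (the
#' coefficient is undefined there, and a zero keeps constant features
#' rankable by their distance term alone).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input: correlation undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  stats::cor(x, y)
}

#' Max-relevance scores
#'
#' Relevance of each feature to the class: MR_i = |PCC(F_i, C)| where F_i is
#' the feature column and C the 0/1 label vector. Zero-variance columns score
#' 0.
#'
#' @param fm Labeled `feature_matrix`.
#' @return Named numeric vector of MR values in [0, 1].
#' @export
mr_scores <- function(fm) {
  require_labels(fm)
  y <- as.numeric(fm$labels)
  apply(fm$x, 2L, function(col) {
    if (stats::sd(col) == 0 || stats::sd(y) == 0) 0 else abs(stats::cor(col, y))
  })
}

# Pairwise Euclidean distances between the COLUMNS of x. Computed from the
# squared differences directly (not the crossprod identity, which loses
# enough precision to cancellation to matter for score ties).
column_distances <- function(x) {
  as.matrix(stats::dist(t(x)))
}

#' Max-distance scores
#'
#' Redundancy term of the MRMD score: MD_i is the mean Euclidean distance
#' from feature column i to every other feature column (distance taken
#' across samples). Larger MD means lower redundancy. By default columns are
#' min-max scaled to [0, 1] first so MD is commensurate with the
#' correlation-bounded MR term; `scale = "none"` uses raw values.
#'
#' @param fm A `feature_matrix` with at least 2 features.
#' @param scale `"minmax"` (default) or `"none"`.
#' @return Named numeric vector of MD values (>= 0).
#' @export
md_scores <- function(fm, scale = c("minmax", "none")) {
  scale <- match.arg(scale)
  x <- fm$x
  m <- ncol(x)
  if (m < 2L) stop("need at least 2 features for distance scores",
                   call. = FALSE)
  if (scale == "minmax") x <- apply(x, 2L, minmax_scale)
  d <- column_distances(x)
  stats::setNames(rowSums(d) / (m - 1L), colnames(fm$x))
}

minmax_scale <- function(col) {
  rng <- range(col)
  if (rng[2] == rng[1]) rep(0, length(col)) else (col - rng[1]) / diff(rng)
}

#' MRMD feature ranking
#'
#' Scores every feature as MR_i + MD_i (relevance to the class plus mean
#' distance to the other features) and ranks features by score, descending.
#' Ties keep the original column order (stable sort).
#'
#' @param fm Labeled `feature_matrix` with >= 2 features.
#' @param scale Column scaling for the MD term; see [md_scores()].
#' @return A data frame of class `mrmd_score_table` with columns `name`,
#'   `MR`, `MD`, `score`, `rank`, sorted by rank.
#' @export
mrmd_rank <- function(fm, scale = "minmax") {
  mr <- mr_scores(fm)
  md <- md_scores(fm, scale = scale)
  score <- mr + md
  ord <- order(-score)  # stable: ties keep column order
  out <- data.frame(name = colnames(fm$x)[ord], MR = unname(mr[ord]),
                    MD = unname(md[ord]), score = unname(score[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  class(out) <- c("mrmd_score_table", "data.frame")
  out
}

#' Incremental (forward) feature-subset selection
#'
#' Walks down the MRMD ranking adding `step` features at a time, evaluates
#' each prefix subset by stratified k-fold cross-validated random-forest
#' accuracy (same folds for every subset size), and returns the smallest
#' subset attaining the maximal accuracy. The full feature set is always
#' among the evaluated sizes, so the chosen accuracy is never below the
#' full-set accuracy on those folds.
#'
#' @param fm Labeled `feature_matrix` (training data).
#' @param table `mrmd_score_table` ranking all features of `fm`.
#' @param folds Cross-validation folds (default 3 inside selection).
#' @param step Subset-size increment (default 1; every size is evaluated as
#'   in the incremental search the ranking was designed for — use e.g. 10
#'   for a coarse, faster search).
#' @param trees Trees per forest evaluation (default 100).
#' @param seed Integer seed controlling folds and forests.
#' @return List of class `mrmd_selection`: `sizes`, `accuracy` (the
#'   accuracy curve), `chosen_features`, `chosen_size`, `chosen_accuracy`.
#' @export
incremental_select <- function(fm, table, folds = 3L, step = 1L,
                               trees = 100L, seed = 1L) {
  require_labels(fm)
  step <- as.integer(step)
  if (step < 1L) stop("`step` must be >= 1", call. = FALSE)
  if (!setequal(table$name, colnames(fm$x))) {
    stop("score table does not rank exactly the features of the matrix",
         call. = FALSE)
  }
  m <- ncol(fm$x)
  sizes <- unique(c(seq(step, m, by = step), m))
  fold_id <- stratified_folds(fm$labels, folds, seed = seed)
  acc <- vapply(sizes, function(s) {
    sub <- table$name[seq_len(s)]
    cv_accuracy(fm, sub, fold_id, trees = trees, seed = seed)
  }, numeric(1))
  best <- max(acc)
  chosen <- sizes[which(acc == best)[1L]]  # smallest size at the max
  structure(list(sizes = sizes, accuracy = acc,
                 chosen_features = table$name[seq_len(chosen)],
                 chosen_size = chosen, chosen_accuracy = best),
            class = "mrmd_selection")
}

#' @export
print.mrmd_selection <- function(x, ...) {
  cat(sprintf("mrmd_selection: chose %d features (CV accuracy %.3f) out of %d\n",
              x$chosen_size, x$chosen_accuracy, max(x$sizes)))
  invisible(x)
}

# Mean held-out accuracy over pre-assigned stratified folds.
cv_accuracy <- function(fm, subset, fold_id, trees, seed) {
  correct <- 0L
  for (f in sort(unique(fold_id))) {
    train <- fm_subset(fm, samples = which(fold_id != f), features = subset)
    test <- fm_subset(fm, samples = which(fold_id == f), features = subset)
    model <- train_forest(train, trees = trees, seed = seed + f)
    pred <- predict_forest(model, test)$class
    correct <- correct + sum(pred == test$labels)
  }
  correct / length(fold_id)
}
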