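#' Train a random-forest classifier
#'
#' Fits a seeded random forest (via ranger, single-threaded for
#' reproducibility) on the requested feature subset. Defaults follow common
#' forest practice: 100 trees, unlimited depth, sqrt(M) candidate features
#' per split. The returned bundle remembers the feature names it was trained
#' on and refuses prediction on a matrix whose feature set differs.
#'
#' @param fm Labeled `feature_matrix` with both classes present.
#' @param subset Optional character vector of feature names to train on
#'   (default: all features); unknown names are an error.
#' @param trees Number of trees (default 100).
#' @param seed Integer seed; predictions are deterministic given it.
#' @return A `forest_model` bundle.
#' @export
train_forest <- function(fm, subset = NULL, trees = 100L, seed = 1L) {
  require_labels(fm)
  if (length(unique(fm$labels)) < 2L) {
    stop("both classes must be present in the training data", call. = FALSE)
  }
  if (!is.null(subset)) fm <- fm_subset(fm, features = subset)
  df <- as.data.frame(fm$x)
  names(df) <- make.names(names(df))  # ranger needs syntactic names
  forest <- ranger::ranger(
    x = df, y = factor(fm$labels, levels = c(0L, 1L)),
    num.trees = as.integer(trees), num.threads = 1L, seed = as.integer(seed),
    verbose = FALSE)
  structure(list(forest = forest, features = colnames(fm$x),
                 trees = as.integer(trees), seed = as.integer(seed)),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("forest_model: %d trees on %d features (seed %d)\n",
              x$trees, length(x$features), x$seed))
  invisible(x)
}

#' Predict with a trained forest
#'
#' Returns the positive-class score of every sample as the fraction of trees
#' voting positive, plus the hard class at the given vote threshold.
#'
#' @param model A `forest_model`.
#' @param fm `feature_matrix` containing at least the model's training
#'   features (any column order; extra columns are ignored, missing ones are
#'   an error).
#' @param threshold Vote fraction at or above which a sample is called
#'   positive (default 0.5).
#' @return List with `score` (vote fractions in [0, 1]) and `class`
#'   (integer 0/1).
#' @export
predict_forest <- function(model, fm, threshold = 0.5) {
  missing <- setdiff(model$features, colnames(fm$x))
  if (length(missing)) {
    stop("feature mismatch with the trained model; missing: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(fm$x[, model$features, drop = FALSE])
  names(df) <- make.names(names(df))
  votes <- stats::predict(model$forest, data = df, predict.all = TRUE,
                          num.threads = 1L)$predictions
  # per-tree predictions are factor-level indices: 1 = "0", 2 = "1"
  score <- rowMeans(votes == 2L)
  list(score = score, class = as.integer(score >= threshold))
}

#' Confusion counts
#'
#' @param truth Integer 0/1 vector of reference labels.
#' @param pred Integer 0/1 vector of predicted labels.
#' @return Named integer vector with TP, FP, FN, TN (class
#'   `confusion_counts`); their sum is the number of samples.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` must have equal length", call. = FALSE)
  }
  structure(c(TP = sum(truth == 1L & pred == 1L),
              FP = sum(truth == 0L & pred == 1L),
              FN = sum(truth == 1L & pred == 0L),
              TN = sum(truth == 0L & pred == 0L)),
            class = "confusion_counts")
}

#' Binary classification metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total,
#' F = 2TP/(2TP+FN+FP) (the F1 harmonic mean), and the Matthews correlation
#' coefficient, with the standard convention that any zero factor in the MCC
#' denominator yields 0 (and 0/0 yields 0 for the ratio metrics).
#'
#' @param cc A `confusion_counts` vector (or any named vector with TP, FP,
#'   FN, TN).
#' @return Named numeric vector with Sn, Sp, Acc, F, MCC.
#' @export
classification_metrics <- function(cc) {
  tp <- as.numeric(cc[["TP"]]); fp <- as.numeric(cc[["FP"]])
  fn <- as.numeric(cc[["FN"]]); tn <- as.numeric(cc[["TN"]])
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  c(Sn = safe_div(tp, tp + fn),
    Sp = safe_div(tn, tn + fp),
    Acc = safe_div(tp + tn, tp + fp + fn + tn),
    F = safe_div(2 * tp, 2 * tp + fn + fp),
    MCC = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / sqrt(mcc_den))
}

#' ROC curve and AUC by trapezoidal integration
#'
#' Sweeps every score threshold, plotting sensitivity against
#' 1 - specificity, and integrates the area with the trapezoid rule. Tied
#' scores cross their threshold simultaneously (one diagonal segment), which
#' makes the result identical to the rank-based Mann-Whitney formulation
#' with ties at half weight.
#'
#' @param labels Integer 0/1 vector; both classes must be present.
#' @param scores Numeric score vector (larger = more positive).
#' @return AUC in [0, 1], with the ROC points attached as attribute
#'   `"roc"` (data frame with columns `fpr` = 1 - Sp and `tpr` = Sn).
#' @export
auc_score <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have equal length", call. = FALSE)
  }
  p <- sum(labels == 1L)
  n <- sum(labels == 0L)
  if (p == 0L || n == 0L) {
    stop("both classes must be present to compute an ROC curve",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == 1L
  last_of_tie <- c(s[-length(s)] != s[-1L], TRUE)
  tpr <- c(0, cumsum(pos)[last_of_tie] / p)
  fpr <- c(0, cumsum(!pos)[last_of_tie] / n)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Evaluate a trained forest on a labeled test set
#'
#' @param model A `forest_model`.
#' @param fm_test Labeled `feature_matrix` with the model's features.
#' @param threshold Vote-fraction decision threshold for the confusion
#'   counts (default 0.5); the ROC/AUC sweeps all thresholds regardless.
#' @return List of class `metrics_report`: `confusion` (TP/FP/FN/TN),
#'   `metrics` (Sn, Sp, Acc, F, MCC, AUC), `roc` (data frame of ROC points),
#'   `scores` (per-sample vote fractions).
#' @export
evaluate <- function(model, fm_test, threshold = 0.5) {
  require_labels(fm_test)
  pred <- predict_forest(model, fm_test, threshold = threshold)
  cc <- confusion_counts(fm_test$labels, pred$class)
  metrics <- classification_metrics(cc)
  auc <- auc_score(fm_test$labels, pred$score)
  # internal consistency: Acc must equal the Sn/Sp-weighted class mix
  p <- sum(fm_test$labels == 1L); n <- sum(fm_test$labels == 0L)
  stopifnot(abs(metrics[["Acc"]] -
                (metrics[["Sn"]] * p + metrics[["Sp"]] * n) / (p + n)) < 1e-12)
  structure(list(confusion = cc,
                 metrics = c(metrics, AUC = as.numeric(auc)),
                 roc = attr(auc, "roc"), scores = pred$score),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cc <- x$confusion
  cat(sprintf("confusion: TP=%d FP=%d FN=%d TN=%d\n",
              cc[["TP"]], cc[["FP"]], cc[["FN"]], cc[["TN"]]))
  cat(paste(sprintf("%s=%.3f", names(x$metrics), x$metrics),
            collapse = "  "), "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation of the forest
#'
#' Splits the samples into stratified folds (class ratio preserved within
#' one sample per fold), trains on k-1 folds and evaluates on the held-out
#' fold, then averages the metrics over folds and pools the confusion
#' counts.
#'
#' @param fm Labeled `feature_matrix`.
#' @param subset Optional feature-name subset.
#' @param folds Number of folds (default 10); each class must have at least
#'   `folds` samples.
#' @param trees,seed Forest parameters; the seed also fixes the folds.
#' @return List of class `cv_report`: `mean_metrics`, `pooled_confusion`,
#'   `fold_reports` (one `metrics_report` per fold), `fold_id`.
#' @export
cross_validate <- function(fm, subset = NULL, folds = 10L, trees = 100L,
                           seed = 1L) {
  require_labels(fm)
  if (!is.null(subset)) fm <- fm_subset(fm, features = subset)
  fold_id <- stratified_folds(fm$labels, folds, seed = seed)
  reports <- lapply(sort(unique(fold_id)), function(f) {
    model <- train_forest(fm_subset(fm, samples = which(fold_id != f)),
                          trees = trees, seed = seed + f)
    evaluate(model, fm_subset(fm, samples = which(fold_id == f)))
  })
  metric_mat <- do.call(rbind, lapply(reports, `[[`, "metrics"))
  pooled <- Reduce(`+`, lapply(reports, function(r) unclass(r$confusion)))
  structure(list(mean_metrics = colMeans(metric_mat),
                 pooled_confusion = structure(pooled,
                                              class = "confusion_counts"),
                 fold_reports = reports, fold_id = fold_id),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d folds\n", length(x$fold_reports)))
  cat(paste(sprintf("%s=%.3f", names(x$mean_metrics), x$mean_metrics),
            collapse = "  "), "\n")
  invisible(x)
}

#' Class-conditional feature means
#'
#' Per-feature mean over positive samples, mean over negative samples, and
#' their signed difference — the group-content comparison used to show that
#' hydrophobic-residue triads are enriched in antioxidant proteins.
#'
#' @param fm Labeled `feature_matrix` with both classes present.
#' @param features Optional feature-name subset.
#' @return Data frame with columns `feature`, `mean_pos`, `mean_neg`,
#'   `difference` (mean_pos - mean_neg).
#' @export
group_feature_means <- function(fm, features = NULL) {
  require_labels(fm)
  if (!is.null(features)) fm <- fm_subset(fm, features = features)
  pos <- fm$labels == 1L
  if (!any(pos) || all(pos)) {
    stop("both classes must be present", call. = FALSE)
  }
  mp <- colMeans(fm$x[pos, , drop = FALSE])
  mn <- colMeans(fm$x[!pos, , drop = FALSE])
  data.frame(feature = colnames(fm$x), mean_pos = unname(mp),
             mean_neg = unname(mn), difference = unname(mp - mn),
             stringsAsFactors = FALSE)
}
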