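# Minority/majority bookkeeping shared by both resamplers.
class_split <- function(fm) {
  require_labels(fm)
  n_pos <- sum(fm$labels == 1L)
  n_neg <- sum(fm$labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to rebalance", call. = FALSE)
  }
  minority <- if (n_pos <= n_neg) 1L else 0L
  list(minority = minority, majority = 1L - minority,
       n_min = min(n_pos, n_neg), n_maj = max(n_pos, n_neg))
}

#' SMOTE oversampling of the minority class
#'
#' Grows the minority class with synthetic samples interpolated between real
#' minority points: each synthetic row is x_i + u * (x_nn - x_i) where x_nn
#' is one of the k nearest minority neighbors of x_i (Euclidean distance on
#' the raw feature values) and u ~ Uniform(0, 1). Original rows are carried
#' through byte-identical; synthetic rows get ids of the form
#' `"<parent>_synth<j>"`. With the default 1:1 target ratio a 200/1500
#' training matrix becomes 1500/1500.
#'
#' @param fm Labeled `feature_matrix` containing both classes.
#' @param k_neighbors Number of minority nearest neighbors to interpolate
#'   toward (default 5); must be smaller than the minority class size.
#' @param target_ratio Desired minority:majority ratio after resampling
#'   (default 1 = balanced).
#' @param seed Integer seed; output is fully reproducible.
#' @return A labeled `feature_matrix` with the synthetic rows appended.
#' @export
smote_oversample <- function(fm, k_neighbors = 5L, target_ratio = 1,
                             seed = 1L) {
  cs <- class_split(fm)
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L || k_neighbors >= cs$n_min) {
    stop("`k_neighbors` must be in [1, minority size - 1]; minority has ",
         cs$n_min, " samples - try a smaller k", call. = FALSE)
  }
  target <- round(cs$n_maj * target_ratio)
  n_new <- target - cs$n_min
  if (n_new <= 0L) return(fm)

  min_idx <- which(fm$labels == cs$minority)
  xm <- fm$x[min_idx, , drop = FALSE]
  # k nearest minority neighbors of each minority point (self excluded)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- vapply(seq_len(nrow(xm)),
               function(i) order(d[i, ])[seq_len(k_neighbors)],
               integer(k_neighbors))
  nn <- if (k_neighbors == 1L) matrix(nn, ncol = 1L) else t(nn)

  new_rows <- with_seed(seed, {
    parents <- sample(nrow(xm), n_new, replace = TRUE)
    picks <- nn[cbind(parents, sample(k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    xm[parents, , drop = FALSE] +
      u * (xm[picks, , drop = FALSE] - xm[parents, , drop = FALSE])
  })
  rownames(new_rows) <- paste0(rownames(new_rows), "_synth", seq_len(n_new))
  feature_matrix(rbind(fm$x, new_rows),
                 c(fm$labels, rep(cs$minority, n_new)))
}

#' Random undersampling of the majority class
#'
#' Subsamples the majority class uniformly without replacement down to the
#' target minority:majority ratio, leaving the minority class untouched.
#' A 200/1500 training matrix becomes 200/200 at the default 1:1 ratio; an
#' already-balanced matrix is returned unchanged.
#'
#' @inheritParams smote_oversample
#' @return A labeled `feature_matrix` with fewer majority rows.
#' @export
random_undersample <- function(fm, target_ratio = 1, seed = 1L) {
  cs <- class_split(fm)
  target <- round(cs$n_min / target_ratio)
  if (target > cs$n_maj) {
    stop("target majority size ", target, " exceeds the majority class (",
         cs$n_maj, ")", call. = FALSE)
  }
  if (target == cs$n_maj) return(fm)
  maj_idx <- which(fm$labels == cs$majority)
  keep_maj <- with_seed(seed, sort(sample(maj_idx, target)))
  keep <- sort(c(which(fm$labels == cs$minority), keep_maj))
  fm_subset(fm, samples = keep)
}
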