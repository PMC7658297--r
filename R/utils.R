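# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `folds` folds such that within every class
#' the fold sizes differ by at most one sample, so each fold preserves the
#' global class ratio up to that granularity.
#'
#' @param labels Integer 0/1 label vector.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed controlling the shuffle.
#' @return Integer vector of fold indices in 1..folds, same length as
#'   `labels`.
#' @export
stratified_folds <- function(labels, folds, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  tab <- table(labels)
  if (any(tab < folds)) {
    stop("smallest class (", min(tab), ") has fewer samples than folds (",
         folds, ")", call. = FALSE)
  }
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}
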