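# Descriptor column names. CKSAAP pair index is 20*rank(a) + rank(b) in
# AA_ALPHABET order (first residue varies slowest); CT triad index is
# (c1-1)*49 + (c2-1)*7 + c3 with classes 1..7 (third class varies fastest).
cksaap_feature_names <- function(gap) {
  paste0(rep(AA_ALPHABET, each = 20L), AA_ALPHABET, ".g", gap)
}

ct_feature_names <- function() {
  paste("CT", rep(1:7, each = 49L), rep(rep(1:7, each = 7L), times = 7L),
        rep(1:7, times = 49L), sep = ".")
}

check_valid_sequence <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  ranks <- match(chars, AA_ALPHABET)
  if (anyNA(ranks)) {
    stop("sequence contains non-standard letter(s): ",
         paste(unique(chars[is.na(ranks)]), collapse = ", "), call. = FALSE)
  }
  ranks
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For a sequence of length N and gap k, every ordered residue pair
#' (position j, position j+k+1) forms one window; there are N-k-1 windows
#' (N-4 at the default k = 3). The descriptor is the frequency of each of
#' the 400 ordered amino-acid pairs among those windows, so the 400 values
#' always sum to 1.
#'
#' @param seq Character scalar over the standard 20-letter alphabet
#'   (uppercase).
#' @param gap Non-negative integer k, the number of residues between the two
#'   pair members. Default 3.
#' @return Named numeric vector of length 400; names are like `"AC.g3"`.
#' @examples
#' v <- cksaap_vector("ACDEFGHIKL", gap = 3)
#' sum(v)            # 1
#' v[v > 0]          # six windows: AF CG DH EI FK GL, each 1/6
#' @export
cksaap_vector <- function(seq, gap = 3L) {
  gap <- as.integer(gap)
  if (gap < 0L) stop("`gap` must be non-negative", call. = FALSE)
  ranks <- check_valid_sequence(toupper(seq))
  n <- length(ranks)
  n_win <- n - gap - 1L
  if (n_win < 1L) {
    stop("sequence of length ", n, " is too short for gap ", gap,
         " (need length >= ", gap + 2L, ")", call. = FALSE)
  }
  a <- ranks[seq_len(n_win)]
  b <- ranks[seq_len(n_win) + gap + 1L]
  counts <- tabulate((a - 1L) * 20L + b, nbins = 400L)
  stats::setNames(counts / n_win, cksaap_feature_names(gap))
}

#' Conjoint-triad (CT) descriptor
#'
#' Maps each residue to one of seven physicochemical classes
#' ([ct_class_map()]) and counts each of the 7^3 = 343 class triads over the
#' N-2 consecutive 3-residue windows. Counts v are normalized as
#' d = (v - min(v)) / max(v) by default (`norm = "max"`); `norm = "range"`
#' divides by max(v) - min(v) instead. Either way all values lie in [0, 1].
#'
#' @param seq Character scalar over the standard alphabet, length >= 3.
#' @param norm Normalization denominator: `"max"` (default) or `"range"`.
#' @return Named numeric vector of length 343 (names like `"CT.1.2.7"`),
#'   with the raw window counts attached as attribute `"counts"`.
#' @examples
#' d <- ct_vector("AAA")
#' d[["CT.1.1.1"]]  # 1: the single window is a class-1,1,1 triad
#' sum(attr(d, "counts"))  # N - 2 = 1
#' @export
ct_vector <- function(seq, norm = c("max", "range")) {
  norm <- match.arg(norm)
  ranks <- check_valid_sequence(toupper(seq))
  n <- length(ranks)
  if (n < 3L) {
    stop("sequence of length ", n, " is too short for the conjoint-triad ",
         "descriptor (need length >= 3)", call. = FALSE)
  }
  cls <- ct_class_map()[AA_ALPHABET][ranks]
  idx <- (cls[1:(n - 2L)] - 1L) * 49L + (cls[2:(n - 1L)] - 1L) * 7L + cls[3:n]
  v <- tabulate(idx, nbins = 343L)
  denom <- if (norm == "max") max(v) else max(v) - min(v)
  d <- if (denom > 0) (v - min(v)) / denom else rep(0, 343L)
  structure(stats::setNames(d, ct_feature_names()), counts = v)
}

#' Extract the combined CKSAAP + CT feature matrix
#'
#' Computes the CKSAAP block (400 columns per gap value) followed by the CT
#' block (343 columns) for every record, giving the combined 743-dimensional
#' representation at the default single gap k = 3. Column naming is
#' deterministic, so repeated runs are bit-identical.
#'
#' @param ds A validated `sequence_dataset` (see [validate_sequences()]).
#' @param gap Integer vector of gap values for the CKSAAP block; default 3.
#'   Multiple gaps concatenate 400 columns each.
#' @param features Which descriptor blocks to include, in order:
#'   subset of `c("cksaap", "ct")`.
#' @param ct_norm CT normalization passed to [ct_vector()].
#' @return A `feature_matrix` labeled from `ds$label` when all labels are
#'   present.
#' @export
extract_features <- function(ds, gap = 3L, features = c("cksaap", "ct"),
                             ct_norm = "max") {
  features <- match.arg(features, several.ok = TRUE)
  header <- c(
    if ("cksaap" %in% features) unlist(lapply(gap, cksaap_feature_names)),
    if ("ct" %in% features) ct_feature_names())
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    tryCatch(
      c(if ("cksaap" %in% features) {
          unlist(lapply(gap, function(g) cksaap_vector(ds$sequence[i], g)))
        },
        if ("ct" %in% features) ct_vector(ds$sequence[i], norm = ct_norm)),
      error = function(e) {
        stop("record '", ds$id[i], "': ", conditionMessage(e), call. = FALSE)
      })
  })
  x <- matrix(0, nrow = nrow(ds), ncol = length(header),
              dimnames = list(ds$id, header))
  for (i in seq_along(rows)) x[i, ] <- rows[[i]]
  labels <- if (nrow(ds) > 0 && !anyNA(ds$label)) ds$label else NULL
  feature_matrix(x, labels)
}
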