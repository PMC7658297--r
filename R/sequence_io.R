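#' Construct a labeled sequence dataset
#'
#' A sequence dataset is a data frame with columns `id`, `sequence` and
#' `label` (integer 1 = positive/antioxidant, 0 = negative, NA = unlabeled),
#' carrying class `sequence_dataset`. Ids must be unique; sequences are
#' uppercased.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param label Optional vector coercible to integer 0/1 (NA allowed),
#'   recycled if length 1.
#' @return A `sequence_dataset`.
#' @export
sequence_dataset <- function(id, sequence, label = NA) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("`id` and `sequence` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate sequence ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  label <- as.integer(label)
  if (length(label) == 1L) label <- rep(label, length(id))
  if (length(label) != length(id)) {
    stop("`label` must have length 1 or length(id)", call. = FALSE)
  }
  if (any(!is.na(label) & !label %in% c(0L, 1L))) {
    stop("labels must be 0, 1 or NA", call. = FALSE)
  }
  structure(data.frame(id = id, sequence = sequence, label = label,
                       stringsAsFactors = FALSE),
            class = c("sequence_dataset", "data.frame"))
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cnt <- dataset_counts(x)
  cat(sprintf("sequence_dataset: %d records (%d positive, %d negative, %d unlabeled)\n",
              nrow(x), cnt[["positive"]], cnt[["negative"]], cnt[["unlabeled"]]))
  if (nrow(x) > 0) {
    len <- nchar(x$sequence)
    cat(sprintf("  length range: %d-%d\n", min(len), max(len)))
  }
  invisible(x)
}

#' Class counts of a sequence dataset
#'
#' @param ds A `sequence_dataset`.
#' @return Named integer vector with elements `positive`, `negative`,
#'   `unlabeled`.
#' @export
dataset_counts <- function(ds) {
  c(positive = sum(ds$label == 1L, na.rm = TRUE),
    negative = sum(ds$label == 0L, na.rm = TRUE),
    unlabeled = sum(is.na(ds$label)))
}

#' Combine sequence datasets
#'
#' @param ... `sequence_dataset` objects with disjoint ids.
#' @return A single `sequence_dataset`.
#' @export
bind_datasets <- function(...) {
  parts <- list(...)
  sequence_dataset(id = unlist(lapply(parts, `[[`, "id")),
                   sequence = unlist(lapply(parts, `[[`, "sequence")),
                   label = unlist(lapply(parts, `[[`, "label")))
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file into a
#' [sequence_dataset()]. Sequences are uppercased; the record id is the first
#' whitespace-delimited token of the header. An empty file yields an empty
#' dataset with a warning.
#'
#' @param path Path to a FASTA file.
#' @param label Optional label (1 = positive, 0 = negative) applied to every
#'   record, e.g. when positives and negatives live in separate files.
#' @return A `sequence_dataset`.
#' @export
read_fasta <- function(path, label = NA) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(sequence_dataset(character(0), character(0), integer(0)))
  }
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (", path, "): line 1 does not start with '>': ",
         substr(first, 1, 40), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA (", path, "): ",
                             conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))
  sequence_dataset(id = ids, sequence = as.character(set), label = label)
}

#' Write a sequence dataset to FASTA
#'
#' @param ds A `sequence_dataset`.
#' @param path Output file path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path, width = 60L) {
  set <- Biostrings::BStringSet(ds$sequence)
  names(set) <- ds$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Validate sequences against the standard amino-acid alphabet
#'
#' Records containing any letter outside the 20 standard amino acids
#' (ambiguity codes B/X/Z, the rare J/O/U, gap `-` and stop `*`) are either
#' dropped with a message or trigger an error, mirroring the curation rule
#' that excludes ambiguous proteins from a benchmark set.
#'
#' @param ds A `sequence_dataset`.
#' @param policy `"drop"` removes offending records and reports the count;
#'   `"error"` aborts at the first offending record, naming it and the letter.
#' @return The validated (possibly reduced) `sequence_dataset`. Empty
#'   sequences count as invalid.
#' @export
validate_sequences <- function(ds, policy = c("drop", "error")) {
  policy <- match.arg(policy)
  ok_pattern <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$")
  ok <- grepl(ok_pattern, ds$sequence)
  if (all(ok)) return(ds)
  if (policy == "error") {
    i <- which(!ok)[1L]
    bad <- setdiff(strsplit(ds$sequence[i], "")[[1]], AA_ALPHABET)
    stop("record '", ds$id[i], "' contains non-standard letter(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  message(sum(!ok), " record(s) dropped for non-standard letters")
  out <- ds[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("sequence_dataset", "data.frame"))
}

#' Seeded stratified train/test split
#'
#' Splits a labeled dataset into train and test parts with the requested
#' number of test records per class, sampling without replacement under a
#' fixed seed. No claim is made to reproduce any published split.
#'
#' @param ds Labeled `sequence_dataset`.
#' @param n_test_pos,n_test_neg Test-set class sizes.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, id-disjoint.
#' @export
stratified_split <- function(ds, n_test_pos, n_test_neg, seed = 1L) {
  pos <- which(ds$label == 1L)
  neg <- which(ds$label == 0L)
  if (n_test_pos > length(pos) || n_test_neg > length(neg)) {
    stop("requested test sizes exceed class sizes", call. = FALSE)
  }
  test_idx <- with_seed(seed, c(sample(pos, n_test_pos),
                                sample(neg, n_test_neg)))
  as_ds <- function(d) {
    rownames(d) <- NULL
    structure(d, class = c("sequence_dataset", "data.frame"))
  }
  list(train = as_ds(ds[-test_idx, , drop = FALSE]),
       test = as_ds(ds[test_idx, , drop = FALSE]))
}
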