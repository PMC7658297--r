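#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in the fixed order used for every
#' position-dependent feature index in this package. All descriptor column
#' orderings (CKSAAP pairs, CT triads) are derived from this vector; changing
#' it would silently re-map feature names, so it is exported as a constant.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Letters that mark a sequence as ambiguous/non-standard. B/X/Z are the
# classic ambiguity codes; J/O/U, gap and stop are treated identically since
# the descriptors are undefined for them.
NONSTANDARD_LETTERS <- c("B", "X", "Z", "J", "O", "U", "*", "-")

#' Conjoint-triad class map
#'
#' Assignment of the 20 standard amino acids to the seven physicochemical
#' classes of the conjoint-triad descriptor, grouped by side-chain dipole and
#' volume: 1 = \{A,G,V\}, 2 = \{I,L,F,P\}, 3 = \{Y,M,T,S\}, 4 = \{H,N,Q,W\},
#' 5 = \{R,K\}, 6 = \{D,E\}, 7 = \{C\}. Classes 1 and 2 collect the
#' hydrophobic residues whose triads carry most of the antioxidant signal.
#'
#' @return Named integer vector mapping each one-letter residue code to its
#'   class index in 1..7.
#' @examples
#' ct_class_map()[["C"]]  # cysteine sits alone in class 7
#' @export
ct_class_map <- function() {
  c(A = 1L, G = 1L, V = 1L,
    I = 2L, L = 2L, F = 2L, P = 2L,
    Y = 3L, M = 3L, T = 3L, S = 3L,
    H = 4L, N = 4L, Q = 4L, W = 4L,
    R = 5L, K = 5L,
    D = 6L, E = 6L,
    C = 7L)
}
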