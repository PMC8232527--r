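#' @useDynLib aptgen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data
#' @importFrom stats setNames
#' @importFrom ranger ranger
NULL

#' Sequence alphabets
#'
#' The four RNA bases and the twenty standard amino acids, in the fixed
#' lexicographic order used throughout the package (feature vectors are
#' ordered over these alphabets, so serialized models are portable).
#'
#' @return Character vector of single-letter residue codes.
#' @export
#' @examples
#' rna_alphabet()
#' protein_alphabet()
rna_alphabet <- function() c("A", "C", "G", "U")

#' @rdname rna_alphabet
#' @export
protein_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Normalize a nucleotide sequence to RNA
#'
#' Upper-cases the input and replaces every T (thymine) with U (uracil),
#' so DNA and RNA aptamer records share one alphabet before encoding.
#' Ambiguity codes (N, R, ...) are rejected rather than imputed.
#'
#' @param seq A single nucleotide string over A/C/G/T/U, any case.
#' @return The normalized RNA string (same length, upper case, no T).
#' @export
#' @examples
#' normalize_nucleotides("ACGT")  # "ACGU"
#' normalize_nucleotides("acgu")  # "ACGU"
normalize_nucleotides <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort("`seq` must be a single non-empty string.", class = "aptgen_invalid_alphabet")
  }
  up <- toupper(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "U"))
  if (length(bad) > 0L) {
    abort(
      sprintf("invalid nucleotide '%s' at position %d", chars[bad[1L]], bad[1L]),
      class = "aptgen_invalid_alphabet"
    )
  }
  gsub("T", "U", up, fixed = TRUE)
}

#' Validate a protein sequence
#'
#' Upper-cases and checks that every residue is one of the 20 standard
#' amino acids; non-standard residues (B, J, O, U, X, Z, ...) fail fast
#' with the offending position.
#'
#' @param seq A single amino-acid string.
#' @return The validated upper-case protein string.
#' @export
normalize_protein <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort("`seq` must be a single non-empty string.", class = "aptgen_invalid_alphabet")
  }
  up <- toupper(seq)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% protein_alphabet())
  if (length(bad) > 0L) {
    abort(
      sprintf("invalid amino acid '%s' at position %d", chars[bad[1L]], bad[1L]),
      class = "aptgen_invalid_alphabet"
    )
  }
  up
}

# Split a sequence into its overlapping k-mers (character vector,
# length L - k + 1). Internal workhorse shared by all encoders.
seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) {
    abort(sprintf("sequence of length %d is too short for k = %d", L, k),
          class = "aptgen_too_short")
  }
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# All |alphabet|^k units in lexicographic order.
all_kmers <- function(alphabet, k) {
  if (k == 1L) return(alphabet)
  grids <- rev(rep(list(alphabet), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}
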