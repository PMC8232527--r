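#' Load a shipped physicochemical property table
#'
#' Property tables supply the per-unit numeric scales used by the
#' covariance (DAC/DCC/TAC/TCC and concatenations) and pseudo-composition
#' (PseKNC, PseAAC) encoders. Tables are shipped as plain TSV
#' (`unit`, `property`, `value`) with a schema-version comment header and
#' can be overridden by passing a file of the same layout.
#'
#' Values are standardized at load time: within each property, to mean 0
#' and variance 1 across the alphabet's units, the form required by the
#' correlation terms of the covariance and pseudo-composition encoders.
#'
#' Shipped ids:
#' \describe{
#'   \item{`rna_dinucleotide`}{16 dinucleotides x 3 scales (Watson-Crick
#'     hydrogen-bond count, purine indicator, nucleoside monophosphate
#'     mass), each k-mer value the mean over its constituent bases.}
#'   \item{`rna_trinucleotide`}{the 64 trinucleotides, same construction.}
#'   \item{`amino_acid`}{20 residues x Kyte-Doolittle hydropathy,
#'     Hopp-Woods hydrophilicity, and side-chain mass (the classic
#'     pseudo amino-acid composition triple).}
#' }
#'
#' @param id One of `"rna_dinucleotide"`, `"rna_trinucleotide"`,
#'   `"amino_acid"`, or a path to a TSV file in the same layout.
#' @param standardize Standardize each property across units (default TRUE).
#' @return A `property_table`: a tibble with columns `unit` and one column
#'   per property, plus attributes `id` and `standardized`.
#' @export
#' @examples
#' tab <- property_table("rna_dinucleotide")
#' colMeans(as.matrix(tab[-1]))  # ~0 after standardization
property_table <- function(id = "rna_dinucleotide", standardize = TRUE) {
  shipped <- c(
    rna_dinucleotide  = "rna_dinucleotide_properties.tsv",
    rna_trinucleotide = "rna_trinucleotide_properties.tsv",
    amino_acid        = "amino_acid_properties.tsv"
  )
  path <- if (id %in% names(shipped)) {
    system.file("extdata", shipped[[id]], package = "aptgen", mustWork = TRUE)
  } else if (file.exists(id)) {
    id
  } else {
    abort(sprintf("unknown property table '%s'", id), class = "aptgen_bad_table")
  }
  long <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("unit", "property", "value") %in% names(long))) {
    abort("property table must have columns unit, property, value",
          class = "aptgen_bad_table")
  }
  wide <- tidyr::pivot_wider(tibble::as_tibble(long),
                             names_from = "property", values_from = "value")
  wide <- dplyr::arrange(wide, .data$unit)
  if (standardize) {
    for (p in setdiff(names(wide), "unit")) {
      v <- wide[[p]]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) {
        abort(sprintf("property '%s' is constant across units", p),
              class = "aptgen_bad_table")
      }
      wide[[p]] <- (v - mean(v)) / s
    }
  }
  structure(wide, id = id, standardized = standardize,
            class = c("property_table", class(wide)))
}

# property matrix (units x properties) with unit rownames
ptab_matrix <- function(table) {
  m <- as.matrix(table[setdiff(names(table), "unit")])
  rownames(m) <- table$unit
  m
}

#' Composition-Transition-Distribution residue groupings
#'
#' The canonical seven physicochemical attributes (hydrophobicity, van der
#' Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity, solvent accessibility), each partitioning the 20 standard
#' amino acids into three groups. Shipped as a TSV; a replacement file in
#' the same layout may be supplied.
#'
#' @param path Optional path to an alternative grouping TSV.
#' @return Tibble with columns `attribute`, `group` (1-3), `residues`.
#' @export
ctd_groups <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "ctd_groups.tsv", package = "aptgen", mustWork = TRUE)
  g <- tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                           stringsAsFactors = FALSE))
  stopifnot(all(c("attribute", "group", "residues") %in% names(g)))
  g
}

#' Conjoint-triad residue classes
#'
#' The canonical 7-class partition of the amino acids by dipole and
#' side-chain volume, used by the protein conjoint-triad encoder. The RNA
#' variant treats each of the four bases as its own class.
#'
#' @param alphabet `"protein"` (7 classes) or `"rna"` (4 identity classes).
#' @return Named integer vector mapping each residue to its class index.
#' @export
triad_classes <- function(alphabet = c("protein", "rna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "rna") {
    return(setNames(1:4, rna_alphabet()))
  }
  path <- system.file("extdata", "triad_classes.tsv", package = "aptgen",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- integer(0)
  for (i in seq_len(nrow(tab))) {
    res <- strsplit(tab$residues[i], "", fixed = TRUE)[[1L]]
    out[res] <- tab$class[i]
  }
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
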