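# Fixed-length feature encodings for variable-length RNA and protein
# sequences. Nine aptamer families (DAC, DCC, DACC, TAC, TCC, TACC,
# PseKNC k = 2/3, iCTF) and six protein families (AAC, DPC, TPC, PseAAC,
# CTD, iCTF); every encoder's output dimension is a pure function of its
# spec, never of the sequence length.

.ptab_cache <- new.env(parent = emptyenv())

cached_property_table <- function(id) {
  if (is.null(.ptab_cache[[id]])) .ptab_cache[[id]] <- property_table(id)
  .ptab_cache[[id]]
}

#' k-mer composition of a sequence
#'
#' Relative frequencies of all overlapping k-mers in fixed lexicographic
#' unit order. Covers amino-acid composition (k = 1), dipeptide (k = 2)
#' and tripeptide (k = 3) composition, and the k-tuple block of PseKNC.
#'
#' @param seq A single normalized sequence string.
#' @param k Word size (1, 2 or 3).
#' @param alphabet `"rna"` or `"protein"`.
#' @return Named numeric vector of length `|alphabet|^k`; entries are
#'   `count / (L - k + 1)` and sum to 1.
#' @export
#' @examples
#' kmer_frequencies("ACGU", 1, "rna")
kmer_frequencies <- function(seq, k, alphabet = c("rna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(k %in% 1:3)
  alph <- if (alphabet == "rna") rna_alphabet() else protein_alphabet()
  kms <- seq_kmers(seq, k)
  counts <- tabulate(match(kms, all_kmers(alph, k)), nbins = length(alph)^k)
  setNames(counts / length(kms), all_kmers(alph, k))
}

#' Auto-covariance of a physicochemical property signal
#'
#' For each property `p` in the table and each lag `l` in `1:max_lag`,
#' computes `AC(p, l) = mean_i[(P_p(i) - Pbar_p)(P_p(i+l) - Pbar_p)]`
#' over the sequence's overlapping k-mer units, where `Pbar_p` is the
#' sequence mean of the property and the divisor is `L' - l` (with `L'`
#' the number of units). Dinucleotide units give DAC, trinucleotide TAC.
#'
#' @param seq Normalized RNA string.
#' @param unit_size 2 (dinucleotide) or 3 (trinucleotide).
#' @param table A [property_table()]; defaults to the shipped table for
#'   the unit size.
#' @param max_lag Maximum correlation distance (default 2).
#' @return Named numeric vector, property-major, lag-minor; length
#'   `n_properties * max_lag`.
#' @export
auto_covariance <- function(seq, unit_size = 2, table = NULL, max_lag = 2) {
  stopifnot(unit_size %in% 2:3, max_lag >= 1)
  if (nchar(seq) <= unit_size + max_lag) {
    abort(sprintf("sequence of length %d too short for unit size %d, lag %d",
                  nchar(seq), unit_size, max_lag), class = "aptgen_too_short")
  }
  table <- table %||% cached_property_table(
    if (unit_size == 2) "rna_dinucleotide" else "rna_trinucleotide")
  pm <- ptab_matrix(table)
  units <- seq_kmers(seq, unit_size)
  P <- pm[units, , drop = FALSE]
  Lp <- nrow(P)
  out <- numeric(0)
  for (p in colnames(pm)) {
    v <- P[, p] - mean(P[, p])
    ac <- vapply(seq_len(max_lag), function(l) {
      sum(v[seq_len(Lp - l)] * v[(1 + l):Lp]) / (Lp - l)
    }, numeric(1))
    out <- c(out, setNames(ac, paste0(p, ".lag", seq_len(max_lag))))
  }
  out
}

#' Cross-covariance between pairs of property signals
#'
#' Same centered-product form as [auto_covariance()] but across all
#' ordered property pairs `p != q`: property `p` at position `i`,
#' property `q` at position `i + l`.
#'
#' @inheritParams auto_covariance
#' @return Named numeric vector, pair-major, lag-minor; length
#'   `n_properties * (n_properties - 1) * max_lag`.
#' @export
cross_covariance <- function(seq, unit_size = 2, table = NULL, max_lag = 2) {
  stopifnot(unit_size %in% 2:3, max_lag >= 1)
  if (nchar(seq) <= unit_size + max_lag) {
    abort(sprintf("sequence of length %d too short for unit size %d, lag %d",
                  nchar(seq), unit_size, max_lag), class = "aptgen_too_short")
  }
  table <- table %||% cached_property_table(
    if (unit_size == 2) "rna_dinucleotide" else "rna_trinucleotide")
  pm <- ptab_matrix(table)
  if (ncol(pm) < 2) {
    abort("cross-covariance needs a table with at least 2 properties",
          class = "aptgen_bad_table")
  }
  units <- seq_kmers(seq, unit_size)
  P <- pm[units, , drop = FALSE]
  P <- sweep(P, 2, colMeans(P))
  Lp <- nrow(P)
  out <- numeric(0)
  for (p in colnames(pm)) {
    for (q in colnames(pm)) {
      if (p == q) next
      cc <- vapply(seq_len(max_lag), function(l) {
        sum(P[seq_len(Lp - l), p] * P[(1 + l):Lp, q]) / (Lp - l)
      }, numeric(1))
      out <- c(out, setNames(cc, paste0(p, ".", q, ".lag", seq_len(max_lag))))
    }
  }
  out
}

# mean squared property difference between two unit rows (standardized
# table); the correlation kernel shared by PseKNC and PseAAC
theta_kernel <- function(P, i, j) {
  d <- P[i, ] - P[j, ]
  mean(d * d)
}

# sequence-order correlation factors theta_1..theta_lambda over a unit
# property matrix P (units in sequence order)
theta_factors <- function(P, lambda) {
  Lp <- nrow(P)
  vapply(seq_len(lambda), function(j) {
    idx <- seq_len(Lp - j)
    D <- P[idx, , drop = FALSE] - P[idx + j, , drop = FALSE]
    mean(rowMeans(D * D))
  }, numeric(1))
}

#' Pseudo k-tuple nucleotide composition (PseKNC)
#'
#' The `4^k` k-tuple frequencies augmented with `lambda` sequence-order
#' correlation factors. Factor `theta_j` is the mean, over all unit
#' positions `i`, of the squared-difference correlation between the
#' (standardized) property vectors of the k-mer units at `i` and `i + j`.
#' Both blocks share the normalizer `sum(f) + w * sum(theta)` so the full
#' vector sums to 1.
#'
#' @param seq Normalized RNA string of length at least `k + lambda`.
#' @param k Tuple size, 2 or 3.
#' @param lambda Number of correlation tiers (default 2).
#' @param w Weight of the correlation block in `[0, 1]` (default 0.05).
#' @param table Property table for the k-mer units.
#' @return Named numeric vector of length `4^k + lambda`, summing to 1.
#' @export
pseknc <- function(seq, k = 3, lambda = 2, w = 0.05, table = NULL) {
  stopifnot(k %in% 2:3, lambda >= 1, w >= 0, w <= 1)
  if (nchar(seq) < k + lambda) {
    abort(sprintf("sequence of length %d too short for k = %d, lambda = %d",
                  nchar(seq), k, lambda), class = "aptgen_too_short")
  }
  table <- table %||% cached_property_table(
    if (k == 2) "rna_dinucleotide" else "rna_trinucleotide")
  pm <- ptab_matrix(table)
  f <- kmer_frequencies(seq, k, "rna")
  units <- seq_kmers(seq, k)
  theta <- theta_factors(pm[units, , drop = FALSE], lambda)
  denom <- sum(f) + w * sum(theta)
  c(f / denom, setNames(w * theta / denom, paste0("theta", seq_len(lambda))))
}

#' Pseudo amino-acid composition (PseAAC, type I)
#'
#' The 20 amino-acid frequencies augmented with `lambda` sequence-order
#' correlation factors computed from standardized hydropathy,
#' hydrophilicity and side-chain mass, all normalized to sum to 1.
#'
#' @param seq Validated protein string, longer than `lambda`.
#' @param lambda Number of correlation tiers (default 10).
#' @param w Weight factor (default 0.05).
#' @param table Amino-acid property table (default: shipped scales).
#' @return Named numeric vector of length `20 + lambda`, summing to 1.
#' @export
pseaac <- function(seq, lambda = 10, w = 0.05, table = NULL) {
  stopifnot(lambda >= 1, w >= 0, w <= 1)
  if (nchar(seq) <= lambda) {
    abort(sprintf("sequence of length %d too short for lambda = %d",
                  nchar(seq), lambda), class = "aptgen_too_short")
  }
  table <- table %||% cached_property_table("amino_acid")
  pm <- ptab_matrix(table)
  f <- kmer_frequencies(seq, 1, "protein")
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  theta <- theta_factors(pm[res, , drop = FALSE], lambda)
  denom <- sum(f) + w * sum(theta)
  c(f / denom, setNames(w * theta / denom, paste0("theta", seq_len(lambda))))
}

#' Conjoint-triad features (iCTF variant)
#'
#' Residues are mapped to physicochemical classes (the canonical 7-class
#' amino-acid partition; for RNA each base is its own class), all class
#' triads over a sliding window of 3 are counted, and counts are min-max
#' normalized as `(f - f_min) / f_max`, placing every entry in `[0, 1]`.
#'
#' @param seq Normalized sequence string of length at least 3.
#' @param alphabet `"rna"` (dimension 64) or `"protein"` (dimension 343).
#' @return Named numeric vector over all class triads.
#' @export
conjoint_triad <- function(seq, alphabet = c("rna", "protein")) {
  alphabet <- match.arg(alphabet)
  cls <- triad_classes(alphabet)
  nc <- max(cls)
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(res) < 3L) {
    abort("conjoint triads need a sequence of length >= 3",
          class = "aptgen_too_short")
  }
  ci <- cls[res]
  if (anyNA(ci)) {
    abort(sprintf("residue '%s' not covered by the class table",
                  res[which(is.na(ci))[1L]]), class = "aptgen_invalid_alphabet")
  }
  n <- length(ci)
  idx <- (ci[1:(n - 2)] - 1L) * nc * nc + (ci[2:(n - 1)] - 1L) * nc + ci[3:n]
  counts <- tabulate(idx, nbins = nc^3)
  labs <- all_kmers(as.character(seq_len(nc)), 3)
  setNames((counts - min(counts)) / max(counts), paste0("t", labs))
}

#' Composition-Transition-Distribution (CTD) protein descriptor
#'
#' For each of 7 physicochemical attributes whose 3 residue groups
#' partition the amino acids: 3 group fractions (composition), 3
#' adjacent-pair cross-group frequencies (transition), and, for each
#' group, the sequence positions of its first, 25%, 50%, 75% and 100%
#' occurrence as fractions of the length (distribution; zeros when the
#' group is absent). 21 values per attribute, 147 in total.
#'
#' @param seq Validated protein string of length at least 2.
#' @param groups Grouping table from [ctd_groups()].
#' @return Named numeric vector of length 147.
#' @export
ctd_features <- function(seq, groups = NULL) {
  groups <- groups %||% ctd_groups()
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(res)
  if (L < 2L) abort("CTD needs a sequence of length >= 2", class = "aptgen_too_short")
  out <- numeric(0)
  for (attr_name in unique(groups$attribute)) {
    ga <- groups[groups$attribute == attr_name, ]
    map <- integer(0)
    for (i in seq_len(nrow(ga))) {
      map[strsplit(ga$residues[i], "", fixed = TRUE)[[1L]]] <- ga$group[i]
    }
    g <- map[res]
    comp <- tabulate(g, nbins = 3L) / L
    pairs_ <- paste0(pmin(g[-L], g[-1L]), pmax(g[-L], g[-1L]))
    trans <- vapply(c("12", "13", "23"),
                    function(p) sum(pairs_ == p) / (L - 1L), numeric(1))
    dist <- numeric(0)
    for (grp in 1:3) {
      occ <- which(g == grp)
      n <- length(occ)
      d <- if (n == 0L) rep(0, 5) else
        occ[c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * n))] / L
      dist <- c(dist, setNames(d, paste0(attr_name, ".D", grp, ".",
                                         c("first", "q25", "q50", "q75", "q100"))))
    }
    out <- c(out,
             setNames(comp, paste0(attr_name, ".C", 1:3)),
             setNames(trans, paste0(attr_name, ".T", c("12", "13", "23"))),
             dist)
  }
  out
}

#' Construct an encoder specification
#'
#' An `encoder_spec` pins down one encoding family and its parameters;
#' the output dimension is a pure function of the spec. Aptamer families:
#' `DAC`, `DCC`, `DACC`, `TAC`, `TCC`, `TACC`, `PseKNC` (k = 2 or 3),
#' `iCTF`. Protein families: `AAC`, `DPC`, `TPC`, `PseAAC`, `CTD`,
#' `iCTF`.
#'
#' @param name Encoder family name (see above).
#' @param alphabet `"rna"` or `"protein"`; required for `iCTF`, inferred
#'   for all other names.
#' @param k Tuple size for `PseKNC` (2 or 3).
#' @param lag Maximum lag for the covariance families (default 2).
#' @param lambda Correlation tiers for `PseKNC` (default 2) and `PseAAC`
#'   (default 10).
#' @param w Correlation weight for `PseKNC`/`PseAAC` (default 0.05).
#' @param property_table_id Override the property table (id or path).
#' @return An `encoder_spec` object.
#' @export
#' @examples
#' encoder_spec("PseKNC", k = 3)
#' encoder_dim(encoder_spec("TPC"))
encoder_spec <- function(name, alphabet = NULL, k = NULL, lag = 2,
                         lambda = NULL, w = 0.05, property_table_id = NULL) {
  apt_names <- c("DAC", "DCC", "DACC", "TAC", "TCC", "TACC", "PseKNC", "iCTF")
  prot_names <- c("AAC", "DPC", "TPC", "PseAAC", "CTD", "iCTF")
  if (!name %in% union(apt_names, prot_names)) {
    abort(sprintf("unknown encoder '%s'", name), class = "aptgen_bad_spec")
  }
  if (is.null(alphabet)) {
    alphabet <- if (name %in% setdiff(apt_names, "iCTF")) "rna"
    else if (name %in% setdiff(prot_names, "iCTF")) "protein"
    else abort("iCTF needs an explicit alphabet", class = "aptgen_bad_spec")
  }
  ok <- (alphabet == "rna" && name %in% apt_names) ||
    (alphabet == "protein" && name %in% prot_names)
  if (!ok) {
    abort(sprintf("encoder '%s' is not defined for alphabet '%s'", name, alphabet),
          class = "aptgen_bad_spec")
  }
  if (name == "PseKNC") {
    k <- k %||% 3
    if (!k %in% 2:3) abort("PseKNC requires k = 2 or 3", class = "aptgen_bad_spec")
    lambda <- lambda %||% 2
  }
  if (name == "PseAAC") lambda <- lambda %||% 10
  structure(
    list(name = name, alphabet = alphabet, k = k, lag = lag,
         lambda = lambda, w = w, property_table_id = property_table_id),
    class = "encoder_spec"
  )
}

#' @export
print.encoder_spec <- function(x, ...) {
  pars <- c(k = x$k, lag = if (grepl("CC|AC", x$name)) x$lag else NULL,
            lambda = x$lambda, w = x$w)
  cat(sprintf("<encoder_spec> %s [%s] dim=%d %s\n", x$name, x$alphabet,
              encoder_dim(x),
              paste(names(pars), unlist(pars), sep = "=", collapse = " ")))
  invisible(x)
}

spec_table <- function(spec, unit_size) {
  if (!is.null(spec$property_table_id)) {
    return(cached_property_table(spec$property_table_id))
  }
  cached_property_table(switch(as.character(unit_size),
    "1" = "amino_acid", "2" = "rna_dinucleotide", "3" = "rna_trinucleotide"))
}

#' Output dimension of an encoder spec
#'
#' @param spec An [encoder_spec()].
#' @return Integer dimension, independent of any sequence.
#' @export
encoder_dim <- function(spec) {
  np <- function(unit_size) ncol(ptab_matrix(spec_table(spec, unit_size)))
  switch(spec$name,
    DAC  = np(2) * spec$lag,
    DCC  = np(2) * (np(2) - 1L) * spec$lag,
    DACC = np(2) * spec$lag + np(2) * (np(2) - 1L) * spec$lag,
    TAC  = np(3) * spec$lag,
    TCC  = np(3) * (np(3) - 1L) * spec$lag,
    TACC = np(3) * spec$lag + np(3) * (np(3) - 1L) * spec$lag,
    PseKNC = 4L^spec$k + spec$lambda,
    AAC  = 20L, DPC = 400L, TPC = 8000L,
    PseAAC = 20L + spec$lambda,
    CTD  = 147L,
    iCTF = if (spec$alphabet == "rna") 64L else 343L
  )
}

#' Encode a sequence with an encoder spec
#'
#' Dispatches to the encoder family named by the spec. Pure: identical
#' inputs always produce bit-identical vectors.
#'
#' @param seq Normalized sequence string matching the spec's alphabet.
#' @param spec An [encoder_spec()].
#' @return Named numeric vector of length `encoder_dim(spec)`.
#' @export
encode_sequence <- function(seq, spec) {
  us <- function(name) if (substr(name, 1, 1) == "T") 3L else 2L
  switch(spec$name,
    DAC = , TAC = auto_covariance(seq, us(spec$name),
                                  spec_table(spec, us(spec$name)), spec$lag),
    DCC = , TCC = cross_covariance(seq, us(spec$name),
                                   spec_table(spec, us(spec$name)), spec$lag),
    DACC = , TACC = {
      u <- us(spec$name)
      tab <- spec_table(spec, u)
      c(auto_covariance(seq, u, tab, spec$lag),
        cross_covariance(seq, u, tab, spec$lag))
    },
    PseKNC = pseknc(seq, spec$k, spec$lambda, spec$w, spec_table(spec, spec$k)),
    AAC = kmer_frequencies(seq, 1, "protein"),
    DPC = kmer_frequencies(seq, 2, "protein"),
    TPC = kmer_frequencies(seq, 3, "protein"),
    PseAAC = pseaac(seq, spec$lambda, spec$w, spec_table(spec, 1)),
    CTD = ctd_features(seq),
    iCTF = conjoint_triad(seq, spec$alphabet)
  )
}

#' Encode an aptamer-protein pair
#'
#' Concatenates the aptamer and protein feature vectors (aptamer block
#' first), the representation consumed by the interaction classifier.
#'
#' @param aptamer Normalized RNA string.
#' @param protein Validated protein string.
#' @param apt_spec,prot_spec Encoder specs for the two sequences.
#' @return Named numeric vector of length
#'   `encoder_dim(apt_spec) + encoder_dim(prot_spec)`; names are prefixed
#'   `apt.` / `prot.`.
#' @export
encode_pair <- function(aptamer, protein, apt_spec, prot_spec) {
  a <- encode_sequence(aptamer, apt_spec)
  p <- encode_sequence(protein, prot_spec)
  setNames(c(a, p), c(paste0("apt.", names(a)), paste0("prot.", names(p))))
}

#' The full encoder grid
#'
#' All 54 combinations of the 9 aptamer and 6 protein encoder families,
#' as a tibble with display labels and spec list-columns. Subsets of this
#' grid drive model selection.
#'
#' @return Tibble with columns `apt_encoder`, `prot_encoder` (labels) and
#'   `apt_spec`, `prot_spec` (list-columns of [encoder_spec()]s).
#' @export
#' @examples
#' nrow(encoder_grid())  # 54
encoder_grid <- function() {
  apt <- list(
    "DAC" = encoder_spec("DAC"), "DCC" = encoder_spec("DCC"),
    "DACC" = encoder_spec("DACC"), "TAC" = encoder_spec("TAC"),
    "TCC" = encoder_spec("TCC"), "TACC" = encoder_spec("TACC"),
    "PseKNC(k=2)" = encoder_spec("PseKNC", k = 2),
    "PseKNC(k=3)" = encoder_spec("PseKNC", k = 3),
    "iCTF" = encoder_spec("iCTF", alphabet = "rna")
  )
  prot <- list(
    "AAC" = encoder_spec("AAC"), "DPC" = encoder_spec("DPC"),
    "TPC" = encoder_spec("TPC"), "PseAAC" = encoder_spec("PseAAC"),
    "CTD" = encoder_spec("CTD"), "iCTF" = encoder_spec("iCTF", alphabet = "protein")
  )
  grid <- tidyr::expand_grid(apt_encoder = names(apt), prot_encoder = names(prot))
  dplyr::mutate(grid,
                apt_spec = unname(apt[.data$apt_encoder]),
                prot_spec = unname(prot[.data$prot_encoder]))
}
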