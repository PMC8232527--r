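# Seeded synthetic aptamer-protein interaction benchmarks with a
# plantable motif rule, so training, model selection and sampling are
# testable end to end with known ground truth and no external data.

#' Configuration for the synthetic interaction benchmark
#'
#' The generator emulates the shape of published interaction
#' benchmarks: RNA aptamers of 20-90 nt, target proteins of 50-400
#' residues, a roughly 1:3 positive:negative class ratio, and an
#' interaction rule in which each protein determines a short RNA motif
#' that its binding aptamers contain. Labels can be flipped with a small
#' probability to emulate annotation noise.
#'
#' @param n_pos,n_neg Positive / negative pair counts (defaults 200/600,
#'   the 1:3 imbalance of the emulated benchmarks).
#' @param n_proteins Size of the shared target-protein pool (default 8;
#'   interaction benchmarks pair many aptamers with a recurring set of
#'   targets, and a shared pool is what makes a train/test split over
#'   pairs meaningful).
#' @param aptamer_length_range,protein_length_range Inclusive length
#'   bounds (defaults 20-90 nt and 50-400 aa).
#' @param motif_length Planted motif length (default 4).
#' @param noise_rate Label-flip probability in `[0, 0.5)` (default 0.1).
#' @param seed Integer seed; the dataset is byte-reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_pos = 200, n_neg = 600, n_proteins = 8,
                             aptamer_length_range = c(20, 90),
                             protein_length_range = c(50, 400),
                             motif_length = 4, noise_rate = 0.1, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1, n_proteins >= 1,
            noise_rate >= 0, noise_rate < 0.5,
            aptamer_length_range[1] <= aptamer_length_range[2],
            protein_length_range[1] <= protein_length_range[2])
  if (motif_length > aptamer_length_range[1]) {
    abort("motif_length exceeds the minimum aptamer length",
          class = "aptgen_bad_config")
  }
  structure(list(n_pos = n_pos, n_neg = n_neg, n_proteins = n_proteins,
                 aptamer_length_range = aptamer_length_range,
                 protein_length_range = protein_length_range,
                 motif_length = motif_length, noise_rate = noise_rate,
                 seed = seed),
            class = "synthetic_config")
}

#' The protein-to-motif hash of the synthetic interaction rule
#'
#' A pure deterministic map: residue `i` of the protein's first
#' `motif_length` residues selects RNA base `ACGU[(utf8 code mod 4) + 1]`
#' at motif position `i`. Ground truth therefore needs no side file -
#' any oracle can recompute it.
#'
#' @param protein Protein sequence(s).
#' @param motif_length Motif length (default 4).
#' @return Character vector of RNA motifs.
#' @export
#' @examples
#' motif_for_protein("MKVL")  # one fixed 4-mer
motif_for_protein <- function(protein, motif_length = 4) {
  vapply(protein, function(p) {
    codes <- utf8ToInt(substr(p, 1, motif_length))
    paste(rna_alphabet()[codes %% 4L + 1L], collapse = "")
  }, "", USE.NAMES = FALSE)
}

random_string <- function(alphabet, len) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic aptamer-protein interaction dataset
#'
#' Proteins are drawn uniformly over the 20 amino acids (a fixed pool of
#' `n_proteins`, shared across records). Each protein maps to an RNA
#' motif via [motif_for_protein()]. Positive pairs carry the protein's
#' motif at a uniformly random aptamer position; negative aptamers are
#' uniform RNA rejection-sampled to be motif-free, so the planted rule
#' is exact. Labels are then flipped with probability `noise_rate`; the
#' pre-noise truth is kept in `label_true`.
#'
#' @param config A [synthetic_config()].
#' @param proteins Optional protein pool to reuse (e.g. to generate a
#'   held-out set over the same targets); default: draw a fresh pool.
#' @return Tibble with columns `aptamer`, `protein`, `label` (possibly
#'   noisy), `label_true`; attributes `motif_map` (tibble `protein`,
#'   `motif`), `proteins`, and `config`.
#' @export
generate_api_dataset <- function(config = synthetic_config(), proteins = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  if (is.null(proteins)) {
    proteins <- vapply(seq_len(cfg$n_proteins), function(i) {
      random_string(protein_alphabet(),
                    sample(seq(cfg$protein_length_range[1],
                               cfg$protein_length_range[2]), 1))
    }, "")
  }
  motifs <- motif_for_protein(proteins, cfg$motif_length)
  n <- cfg$n_pos + cfg$n_neg
  label_true <- rep(c("positive", "negative"), c(cfg$n_pos, cfg$n_neg))
  pidx <- sample.int(length(proteins), n, replace = TRUE)
  aptamer <- character(n)
  for (i in seq_len(n)) {
    m <- motifs[pidx[i]]
    L <- sample(seq(cfg$aptamer_length_range[1], cfg$aptamer_length_range[2]), 1)
    if (label_true[i] == "positive") {
      a <- random_string(rna_alphabet(), L)
      at <- sample.int(L - cfg$motif_length + 1L, 1)
      aptamer[i] <- paste0(substr(a, 1, at - 1), m,
                           substr(a, at + cfg$motif_length, L))
    } else {
      repeat {
        a <- random_string(rna_alphabet(), L)
        if (!grepl(m, a, fixed = TRUE)) break
      }
      aptamer[i] <- a
    }
  }
  flip <- stats::runif(n) < cfg$noise_rate
  label <- ifelse(flip,
                  ifelse(label_true == "positive", "negative", "positive"),
                  label_true)
  out <- tibble::tibble(aptamer = aptamer, protein = proteins[pidx],
                        label = label, label_true = label_true)
  attr(out, "motif_map") <- tibble::tibble(protein = proteins, motif = motifs)
  attr(out, "proteins") <- proteins
  attr(out, "config") <- cfg
  out
}

#' A rigged score function with known ground truth
#'
#' Returns `reward` when the sequence contains `motif`, 0 otherwise: a
#' pure, deterministic stand-in for a trained interaction classifier,
#' used to test that the tree search converges on rewarded sequences.
#'
#' @param motif Non-empty RNA motif.
#' @param reward Score for motif-containing sequences, in `(0, 1]`.
#' @return A scorer function (character vector -> numeric vector).
#' @export
#' @examples
#' sc <- make_rigged_scorer("GGA")
#' sc(c("UGGAU", "UUUUU"))  # 1, 0
make_rigged_scorer <- function(motif, reward = 1) {
  stopifnot(nzchar(motif), reward > 0, reward <= 1)
  force(motif); force(reward)
  function(sequences) {
    ifelse(grepl(motif, sequences, fixed = TRUE), reward, 0)
  }
}
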