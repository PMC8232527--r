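# RNA secondary structure in dot-bracket notation, used only to collapse
# generated candidates that fold identically (keeping the best-scoring
# representative per structure).

#' Predict RNA secondary structure in dot-bracket notation
#'
#' The builtin backend is a Nussinov-style maximum base-pairing dynamic
#' program: admissible pairs are AU/UA, GC/CG and the GU/UG wobble, a
#' hairpin loop must enclose at least 3 unpaired bases, and the
#' traceback is deterministic (pairing preferred over leaving a base
#' unpaired; leftmost admissible partner first). The external backend
#' shells out to an RNAfold-compatible tool and parses its dot-bracket
#' line; it is opt-in and errors loudly when the tool is missing (never
#' a silent fallback). The two backends generally predict different
#' structures (maximum pairing vs minimum free energy); structures are
#' used here only as an identity key for deduplication, so either
#' backend is valid as long as it is used consistently.
#'
#' @param seq Character vector of normalized RNA sequences.
#' @param backend `"builtin"` (default) or `"vienna"`.
#' @param rnafold RNAfold executable for the external backend.
#' @return Character vector of dot-bracket strings, aligned to `seq`.
#' @export
#' @examples
#' fold_rna("GGGAAAACCC")  # "(((....)))"
#' fold_rna("AAAA")        # "...." - nothing can pair
fold_rna <- function(seq, backend = c("builtin", "vienna"),
                     rnafold = "RNAfold") {
  backend <- match.arg(backend)
  seq <- vapply(seq, normalize_nucleotides, "", USE.NAMES = FALSE)
  if (backend == "builtin") {
    return(vapply(seq, .nussinov_fold, "", USE.NAMES = FALSE))
  }
  if (Sys.which(rnafold) == "") {
    abort(sprintf("external backend requested but '%s' was not found", rnafold),
          class = "aptgen_backend_missing")
  }
  out <- system2(rnafold, c("--noPS"), input = seq, stdout = TRUE)
  db <- grep("^[.()]+( |$)", out, value = TRUE)
  db <- sub("^([.()]+).*$", "\\1", db)
  if (length(db) != length(seq) || any(nchar(db) != nchar(seq))) {
    abort("could not parse dot-bracket output from the external folder",
          class = "aptgen_backend_parse")
  }
  db
}

#' Deduplicate candidates by predicted secondary structure
#'
#' Folds every candidate, groups candidates whose dot-bracket strings
#' are exactly identical, keeps the highest-scoring member of each group
#' (ties: lexicographically smallest sequence), and sorts the result by
#' score, descending. Idempotent.
#'
#' @param candidates Tibble with columns `sequence` and `score` (e.g.
#'   from [generate_aptamers()]); extra columns are carried through.
#' @param backend,rnafold Passed to [fold_rna()].
#' @return Tibble with a `dot_bracket` column, one row per distinct
#'   structure, sorted by descending score; attribute `backend` records
#'   the folding backend.
#' @export
dedup_candidates <- function(candidates, backend = c("builtin", "vienna"),
                             rnafold = "RNAfold") {
  backend <- match.arg(backend)
  stopifnot(all(c("sequence", "score") %in% names(candidates)))
  uniq <- unique(candidates$sequence)
  db <- fold_rna(uniq, backend = backend, rnafold = rnafold)
  out <- candidates |>
    dplyr::mutate(dot_bracket = db[match(.data$sequence, uniq)]) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$sequence) |>
    dplyr::distinct(.data$dot_bracket, .keep_all = TRUE) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$sequence)
  attr(out, "backend") <- backend
  out
}

#' Top-k candidates by interaction score
#'
#' The first `k` rows of the score-sorted candidate set (fewer if the
#' set is smaller). Stable: re-invocation returns the same rows.
#'
#' @param candidates Score-sorted candidate tibble (see
#'   [dedup_candidates()]).
#' @param k Number of candidates to keep (default 10).
#' @return Tibble with at most `k` rows, a `rank` column prepended.
#' @export
top_candidates <- function(candidates, k = 10) {
  stopifnot(k >= 1)
  candidates |>
    dplyr::arrange(dplyr::desc(.data$score), .data$sequence) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Plot a candidate set's score profile
#'
#' Interaction score against rank, one panel per scorer if several are
#' present.
#'
#' @param candidates Candidate tibble with a `score` column.
#' @return A ggplot object.
#' @export
plot_candidates <- function(candidates) {
  d <- candidates |>
    dplyr::group_by(dplyr::across(dplyr::any_of("scorer_id"))) |>
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank", y = "interaction score") +
    ggplot2::theme_minimal()
  if ("scorer_id" %in% names(candidates)) {
    p <- p + ggplot2::facet_wrap(~scorer_id)
  }
  p
}

#' Plot a model-selection leaderboard
#'
#' Distribution of held-out MCC per encoder combination across the
#' repeated-training candidates.
#'
#' @param selection An `api_selection` from [select_best_model()].
#' @return A ggplot object.
#' @export
plot_leaderboard <- function(selection) {
  lb <- dplyr::filter(selection$leaderboard, !is.na(.data$mcc))
  ggplot2::ggplot(lb, ggplot2::aes(
    x = interaction(.data$apt_encoder, .data$prot_encoder, sep = " x "),
    y = .data$mcc)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "held-out MCC") +
    ggplot2::theme_minimal()
}
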