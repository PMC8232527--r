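# Readers and writers for the package's plain-text dialects: labelled
# interaction datasets (TSV), protein FASTA, candidate tables
# (TSV/FASTA/Vienna two-line), model archives and run manifests.

#' Read a labelled aptamer-protein interaction dataset
#'
#' TSV with header columns `aptamer_sequence`, `protein_sequence`,
#' `label` (`1`/`0` or `positive`/`negative`); the short forms
#' `aptamer`/`protein` are also accepted. Aptamer T is normalized to U;
#' malformed rows fail with their line number.
#'
#' @param path TSV file path.
#' @return Tibble with columns `aptamer`, `protein`, `label`.
#' @export
read_api_dataset <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  nm <- names(raw)
  pick <- function(...) {
    hit <- intersect(c(...), nm)
    if (length(hit) == 0) {
      abort(sprintf("missing column (%s) in %s", paste(c(...), collapse = "/"),
                    path), class = "aptgen_bad_file")
    }
    raw[[hit[1]]]
  }
  apt <- pick("aptamer_sequence", "aptamer")
  prot <- pick("protein_sequence", "protein")
  lab <- pick("label")
  out <- tibble::tibble(
    aptamer = vapply(seq_along(apt), function(i) {
      tryCatch(normalize_nucleotides(apt[i]), error = function(e) {
        abort(sprintf("%s line %d: %s", path, i + 1L, conditionMessage(e)),
              class = "aptgen_bad_file")
      })
    }, ""),
    protein = vapply(seq_along(prot), function(i) {
      tryCatch(normalize_protein(prot[i]), error = function(e) {
        abort(sprintf("%s line %d: %s", path, i + 1L, conditionMessage(e)),
              class = "aptgen_bad_file")
      })
    }, ""),
    label = as.character(normalize_labels(lab))
  )
  out
}

#' Write a labelled interaction dataset as TSV
#'
#' @param data Tibble with columns `aptamer`, `protein`, `label` (extra
#'   columns are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_api_dataset <- function(data, path) {
  df <- data.frame(aptamer_sequence = data$aptamer,
                   protein_sequence = data$protein,
                   label = as.character(normalize_labels(data$label)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target protein from FASTA
#'
#' @param path FASTA file.
#' @param single Require exactly one record (the generation unit of work
#'   is a single target protein).
#' @return Named character vector of validated protein sequences.
#' @export
read_protein_fasta <- function(path, single = TRUE) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (single && length(recs) != 1L) {
    abort(sprintf("%s contains %d records; supply exactly one target protein per run",
                  path, length(recs)), class = "aptgen_bad_file")
  }
  setNames(vapply(recs, function(r) normalize_protein(as.character(r)), ""),
           names(recs))
}

#' Write candidates as TSV, FASTA and Vienna two-line format
#'
#' The TSV carries `rank`, `sequence`, `score`, `dot_bracket` and
#' `scorer_id`; FASTA ids are `rank_score`; the Vienna file alternates
#' sequence and structure lines.
#'
#' @param candidates Ranked candidate tibble (see [top_candidates()]).
#' @param tsv,fasta,vienna Output paths (NULL to skip a format).
#' @return The TSV path, invisibly.
#' @export
write_candidates <- function(candidates, tsv, fasta = NULL, vienna = NULL) {
  d <- candidates
  if (!"rank" %in% names(d)) d$rank <- seq_len(nrow(d))
  if (!"scorer_id" %in% names(d)) d$scorer_id <- "scorer"
  if (!"dot_bracket" %in% names(d)) d$dot_bracket <- NA_character_
  utils::write.table(
    d[, c("rank", "sequence", "score", "dot_bracket", "scorer_id")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ids <- sprintf("%d_%0.6f", d$rank, d$score)
  if (!is.null(fasta)) {
    seqinr::write.fasta(as.list(d$sequence), ids, fasta)
  }
  if (!is.null(vienna)) {
    writeLines(as.vector(rbind(paste0("> ", ids), d$sequence, d$dot_bracket)),
               vienna)
  }
  invisible(tsv)
}

#' Save / load a trained interaction classifier
#'
#' The archive embeds the forest, both encoder specs, the training seed
#' and the evaluation metrics under a schema version; loading verifies
#' the schema and rejects foreign files.
#'
#' @param model An `api_classifier`.
#' @param path Archive path (`.rds`).
#' @return `save_classifier`: `path` invisibly; `load_classifier`: the
#'   restored `api_classifier`.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "api_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "api_classifier") ||
      !identical(obj$schema, "aptgen-model-v1")) {
    abort(sprintf("%s is not an aptgen model archive (schema aptgen-model-v1)",
                  path), class = "aptgen_bad_file")
  }
  obj
}

# JSON run manifest: resolved configuration, seed, and md5 checksums of
# the input files, sufficient to reproduce the artifact bit for bit.
write_manifest <- function(path, config, inputs = character()) {
  checks <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(config = config, input_md5 = checks),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
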