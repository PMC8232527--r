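# Iterative forward sequence sampling: N rounds of UCT-guided Monte
# Carlo tree search over a directional-base tree. Each round runs M
# iterations (selection, expansion, random playout, scoring,
# backpropagation), emits M full-length scored candidates, and commits
# the best root child's base before the next round.

#' The eight directional bases
#'
#' A directional base is a nucleotide tagged with the side at which it
#' extends the partially built sequence: `"A_"` prepends A, `"_A"`
#' appends A, and so on. The underscore marks where the *rest* of the
#' sequence sits.
#'
#' @return Character vector of the 8 labels, prepend forms first.
#' @export
#' @examples
#' directional_bases()
directional_bases <- function() {
  c("A_", "C_", "G_", "U_", "_A", "_C", "_G", "_U")
}

# integer code (1..8) helpers: 1-4 prepend A,C,G,U; 5-8 append A,C,G,U
code_base <- function(code) rna_alphabet()[(code - 1L) %% 4L + 1L]
code_is_prepend <- function(code) code <= 4L

build_sequence <- function(core, codes) {
  if (length(codes) == 0L) return(core)
  bases <- code_base(codes)
  pre <- code_is_prepend(codes)
  paste0(paste(rev(bases[pre]), collapse = ""), core,
         paste(bases[!pre], collapse = ""))
}

#' Upper Confidence bound applied to Trees (UCT)
#'
#' `s/n + C * sqrt(ln(N_parent) / n)`: mean backed-up score
#' (exploitation) plus a visit-count exploration bonus. Unvisited nodes
#' (`n = 0`) score `+Inf`, so every instantiated child is tried before
#' any is re-exploited.
#'
#' @param s Cumulative backed-up score of the node.
#' @param n Visit count of the node.
#' @param n_parent Visit count of the parent.
#' @param c_explore Exploration constant (default 12).
#' @return UCT score(s); vectorized over its arguments.
#' @export
#' @examples
#' uct(1, 1, 1, 12)            # 1: the exploration term vanishes at ln(1)
#' uct(3, 2, 10, 12)           # 1.5 + 12 * sqrt(log(10) / 2)
uct <- function(s, n, n_parent, c_explore = 12) {
  out <- s / n + c_explore * sqrt(log(n_parent) / n)
  out[n == 0] <- Inf
  out
}

#' Reconstruct a sequence from a directional-base path
#'
#' Applies directional bases in order to a core: append forms
#' concatenate the base on the right, prepend forms on the left. E.g.
#' core `"GAU"` with path `_U, _C, A_, G_` builds
#' GAU -> GAUU -> GAUUC -> AGAUUC -> GAGAUUC.
#'
#' @param core Starting (possibly empty) RNA string.
#' @param path Character vector of directional-base labels (see
#'   [directional_bases()]).
#' @return The reconstructed RNA string of length
#'   `nchar(core) + length(path)`.
#' @export
#' @examples
#' reconstruct("GAU", c("_U", "_C", "A_", "G_"))  # "GAGAUUC"
reconstruct <- function(core, path = character()) {
  if (length(path) == 0L) return(core)
  codes <- match(path, directional_bases())
  if (anyNA(codes)) {
    abort(sprintf("unknown directional base '%s'", path[which(is.na(codes))[1L]]),
          class = "aptgen_bad_base")
  }
  build_sequence(core, codes)
}

# ---- search tree internals -------------------------------------------------
# A node is an environment: kids (list of 8 child envs or NULL), ks/kn
# (cumulative score / visit count of each child slot), nkids. A child's
# own statistics live in its parent's ks/kn slots; the root additionally
# tracks its own visit count n.

mcts_node <- function() {
  e <- new.env(parent = emptyenv())
  e$kids <- vector("list", 8L)
  e$ks <- numeric(8L)
  e$kn <- numeric(8L)
  e$nkids <- 0L
  e$n <- 0
  e
}

# descend by UCT from the root; stops at the first node with < 8
# instantiated children or at the depth limit. Returns the child-slot
# index path. UCT ties are broken uniformly at random.
mcts_select <- function(root, c_explore, limit) {
  node <- root
  n_node <- root$n
  path <- integer(limit)
  depth <- 0L
  while (node$nkids == 8L && depth < limit) {
    u <- node$ks / node$kn + c_explore * sqrt(log(n_node) / node$kn)
    best <- which(u == max(u))
    i <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    depth <- depth + 1L
    path[depth] <- i
    n_node <- node$kn[i]
    node <- node$kids[[i]]
  }
  list(path = path[seq_len(depth)], node = node, depth = depth)
}

# instantiate one uniformly random missing child slot
mcts_expand <- function(node) {
  missing <- which(vapply(node$kids, is.null, logical(1)))
  i <- if (length(missing) > 1L) missing[sample.int(length(missing), 1L)] else missing
  node$kids[[i]] <- mcts_node()
  node$nkids <- node$nkids + 1L
  i
}

# uniform random playout codes from `depth` down to the limit
mcts_simulate <- function(depth, limit) {
  if (depth >= limit) return(integer(0))
  sample.int(8L, limit - depth, replace = TRUE)
}

# add the interaction score to every node slot along the path
mcts_backprop <- function(root, path, score) {
  root$n <- root$n + 1
  node <- root
  for (i in path) {
    node$ks[i] <- node$ks[i] + score
    node$kn[i] <- node$kn[i] + 1
    node <- node$kids[[i]]
  }
  invisible(root)
}

# ---------------------------------------------------------------------------

#' Run one position-selection round of the tree search
#'
#' Performs exactly `m_iter` iterations of
#' selection - expansion - random playout - scoring - backpropagation
#' on a fresh directional-base tree whose depth limit is
#' `length_target - nchar(core)`. Every iteration reconstructs one
#' full-length candidate (core plus tree path plus playout), scores it
#' with the supplied score function, and backs the score up the tree.
#'
#' The committed base for the round is the root child with the highest
#' mean backed-up score `s/n`; ties are broken by the larger visit
#' count, then by the fixed label order of [directional_bases()].
#'
#' @param core Already-committed bases (possibly empty string).
#' @param scorer Function: character vector of RNA sequences ->
#'   interaction scores in `[0, 1]` (see [make_scorer()]).
#' @param length_target Full aptamer length N.
#' @param m_iter Iterations for this round (default 5000).
#' @param c_explore Exploration constant (default 12).
#' @param cache Optional environment memoizing scores by sequence.
#' @return List: `best` (committed label), `best_index`, `candidates`
#'   (tibble `iteration`, `sequence`, `score`, one row per iteration),
#'   `root_children` (label, n, s, mean), `root_visits`.
#' @export
run_round <- function(core, scorer, length_target, m_iter = 5000,
                      c_explore = 12, cache = NULL) {
  if (m_iter < 1) abort("m_iter must be >= 1", class = "aptgen_bad_config")
  limit <- length_target - nchar(core)
  if (limit < 1) abort("core is already at the target length",
                       class = "aptgen_bad_config")
  root <- mcts_node()
  seqs <- character(m_iter)
  scores <- numeric(m_iter)
  for (it in seq_len(m_iter)) {
    sel <- mcts_select(root, c_explore, limit)
    path <- sel$path
    depth <- sel$depth
    if (depth < limit) {
      i <- mcts_expand(sel$node)
      depth <- depth + 1L
      path <- c(path, i)
    }
    sim <- mcts_simulate(depth, limit)
    seq <- build_sequence(core, c(path, sim))
    sc <- if (!is.null(cache) && !is.null(cache[[seq]])) {
      cache[[seq]]
    } else {
      v <- scorer(seq)
      if (is.na(v) || v < 0 || v > 1) {
        abort(sprintf("scorer returned %s for '%s' (must be in [0,1])",
                      format(v), seq), class = "aptgen_bad_score")
      }
      if (!is.null(cache)) cache[[seq]] <- v
      v
    }
    mcts_backprop(root, path, sc)
    seqs[it] <- seq
    scores[it] <- sc
  }
  means <- ifelse(root$kn > 0, root$ks / root$kn, -Inf)
  best_index <- order(-means, -root$kn, seq_along(means))[1L]
  list(
    best = directional_bases()[best_index],
    best_index = best_index,
    candidates = tibble::tibble(iteration = seq_len(m_iter),
                                sequence = seqs, score = scores),
    root_children = tibble::tibble(label = directional_bases(),
                                   n = root$kn, s = root$ks,
                                   mean = ifelse(root$kn > 0,
                                                 root$ks / root$kn, NA_real_)),
    root_visits = root$n
  )
}

#' Generate candidate aptamer sequences for a target
#'
#' The full iterative forward sampler: `length` rounds of [run_round()],
#' each committing one directional base to the growing core, every round
#' scoring `m_per_round` full-length candidates. The raw output holds
#' `length * m_per_round` candidates per score function (before
#' structure deduplication; see [dedup_candidates()]).
#'
#' With several score functions the search is run independently per
#' scorer (reported candidate lists are then typically combined as the
#' top k per scorer).
#'
#' @param scorers A scorer function, or a named list of scorer functions
#'   (see [make_scorer()] / [make_rigged_scorer()]).
#' @param aptamer_length Target aptamer length N (required; candidate
#'   length is a modelling choice, not a default).
#' @param m_per_round Iterations per round M (default 5000).
#' @param c_explore Exploration constant C (default 12).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param verbose Print the committed base per round.
#' @return Tibble with columns `scorer_id`, `round`, `iteration`,
#'   `sequence`, `score`; attributes `committed` (per-round committed
#'   labels and cores) and `config`.
#' @export
#' @examples
#' sc <- make_rigged_scorer("GGA")
#' out <- generate_aptamers(sc, aptamer_length = 6, m_per_round = 30, seed = 1)
#' nrow(out)  # 6 * 30
generate_aptamers <- function(scorers, aptamer_length, m_per_round = 5000,
                              c_explore = 12, seed = 1, verbose = FALSE) {
  n_len <- aptamer_length
  if (n_len < 1) abort("aptamer_length must be >= 1", class = "aptgen_bad_config")
  if (is.function(scorers)) scorers <- list(scorer = scorers)
  if (is.null(names(scorers)) || any(!nzchar(names(scorers)))) {
    names(scorers) <- paste0("scorer", seq_along(scorers))
  }
  set.seed(seed)
  scorer_seeds <- sample.int(.Machine$integer.max - 1L, length(scorers))
  out <- vector("list", length(scorers))
  committed <- vector("list", length(scorers))
  for (si in seq_along(scorers)) {
    set.seed(scorer_seeds[si])
    round_seeds <- sample.int(.Machine$integer.max - 1L, n_len)
    cache <- new.env(parent = emptyenv())
    core <- ""
    parts <- vector("list", n_len)
    bases <- character(n_len)
    for (r in seq_len(n_len)) {
      set.seed(round_seeds[r])
      rr <- run_round(core, scorers[[si]], length_target = n_len,
                      m_iter = m_per_round, c_explore = c_explore,
                      cache = cache)
      parts[[r]] <- dplyr::mutate(rr$candidates, round = r, .before = 1)
      bases[r] <- rr$best
      core <- reconstruct(core, rr$best)
      if (verbose) {
        message(sprintf("[%s] round %d/%d: committed %s -> %s",
                        names(scorers)[si], r, n_len, rr$best, core))
      }
    }
    out[[si]] <- dplyr::mutate(dplyr::bind_rows(parts),
                               scorer_id = names(scorers)[si], .before = 1)
    committed[[si]] <- tibble::tibble(scorer_id = names(scorers)[si],
                                      round = seq_len(n_len), base = bases,
                                      core = vapply(seq_len(n_len), function(r) {
                                        reconstruct("", bases[seq_len(r)])
                                      }, ""))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "committed") <- dplyr::bind_rows(committed)
  attr(res, "config") <- list(aptamer_length = n_len, m_per_round = m_per_round,
                              c_explore = c_explore, seed = seed)
  res
}
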