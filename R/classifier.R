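# Random-forest aptamer-protein interaction (API) classifiers: training,
# confusion-matrix metrics, and the repeated-training MCC-based model
# selection that produces the MCTS score function.

#' Confusion-matrix metrics for binary interaction classification
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, accuracy,
#' Youden's J (`Sen + Spe - 1`) and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any metric
#' whose denominator is zero is reported as 0 and flagged, so model
#' selection survives degenerate candidates instead of aborting.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return One-row tibble: `tp`, `tn`, `fp`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `youden_j`, `mcc`, `degenerate`.
#' @export
#' @examples
#' compute_metrics(tp = 10, tn = 10, fp = 0, fn = 0)  # perfect: all 1
compute_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) {
    abort("no evaluated records (all counts zero)", class = "aptgen_empty_eval")
  }
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else num / den
  }
  sen <- safe_div(tp, tp + fn)
  spe <- safe_div(tn, fp + tn)
  acc <- (tp + tn) / total
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) {
    degenerate <- TRUE
    0
  } else {
    # clamp: the factored denominator can overshoot |1| by an ulp
    max(-1, min(1, (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den))
  }
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sensitivity = sen, specificity = spe, accuracy = acc,
    youden_j = sen + spe - 1, mcc = mcc, degenerate = degenerate
  )
}

# coerce labels to a factor with levels negative < positive
normalize_labels <- function(label) {
  if (is.factor(label)) label <- as.character(label)
  if (is.numeric(label)) label <- ifelse(label > 0, "positive", "negative")
  label <- tolower(as.character(label))
  label[label == "1"] <- "positive"
  label[label == "0"] <- "negative"
  bad <- setdiff(unique(label), c("positive", "negative"))
  if (length(bad) > 0) {
    abort(sprintf("unrecognized label '%s'", bad[1L]), class = "aptgen_bad_label")
  }
  factor(label, levels = c("negative", "positive"))
}

# encode every (aptamer, protein) pair of a dataset into a feature matrix
encode_dataset <- function(data, apt_spec, prot_spec) {
  stopifnot(all(c("aptamer", "protein") %in% names(data)))
  d <- encoder_dim(apt_spec) + encoder_dim(prot_spec)
  # proteins recur across pairs; encode each distinct one once
  prot_cache <- new.env(parent = emptyenv())
  prot_feat <- function(p) {
    key <- p
    v <- prot_cache[[key]]
    if (is.null(v)) {
      v <- encode_sequence(p, prot_spec)
      prot_cache[[key]] <- v
    }
    v
  }
  out <- matrix(NA_real_, nrow = nrow(data), ncol = d)
  for (i in seq_len(nrow(data))) {
    out[i, ] <- tryCatch(
      c(encode_sequence(data$aptamer[i], apt_spec), prot_feat(data$protein[i])),
      error = function(e) {
        abort(sprintf("encoding failed for record %d: %s", i, conditionMessage(e)),
              class = "aptgen_encoding_error")
      }
    )
  }
  colnames(out) <- paste0("f", seq_len(d))
  out
}

#' Train a random-forest interaction classifier
#'
#' Fits a probability forest on pair encodings of a labelled
#' aptamer-protein dataset. Class weights are inversely proportional to
#' class frequencies ("balanced"), compensating the roughly 1:3
#' positive:negative imbalance typical of interaction benchmarks.
#' Deterministic given `seed` (single-threaded).
#'
#' @param data Tibble/data frame with columns `aptamer` (RNA, normalized
#'   or DNA - T is converted to U), `protein`, `label` (1/0 or
#'   positive/negative).
#' @param apt_spec,prot_spec Encoder specs ([encoder_spec()]).
#' @param n_trees Number of decision trees.
#' @param seed Integer seed for the forest.
#' @param balanced Use inverse-frequency class weights (default TRUE).
#' @return An `api_classifier` object.
#' @export
train_forest <- function(data, apt_spec, prot_spec, n_trees = 100, seed = 1,
                         balanced = TRUE) {
  data <- dplyr::mutate(tibble::as_tibble(data),
                        aptamer = vapply(.data$aptamer, normalize_nucleotides, ""))
  y <- normalize_labels(data$label)
  if (length(unique(y)) < 2) {
    abort("training data must contain both classes", class = "aptgen_untrainable")
  }
  x <- encode_dataset(data, apt_spec, prot_spec)
  cw <- if (balanced) {
    freq <- table(y)
    w <- as.numeric(sum(freq) / (2 * freq))
    setNames(w, names(freq))
  } else NULL
  forest <- ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = n_trees, probability = TRUE,
    class.weights = cw, seed = seed, num.threads = 1
  )
  structure(
    list(forest = forest, apt_spec = apt_spec, prot_spec = prot_spec,
         n_trees = n_trees, training_seed = seed, balanced = balanced,
         n_features = ncol(x), metrics = NULL,
         schema = "aptgen-model-v1"),
    class = "api_classifier"
  )
}

#' @export
print.api_classifier <- function(x, ...) {
  cat(sprintf("<api_classifier> %d trees, %s x %s (%d features), seed %d\n",
              x$n_trees, x$apt_spec$name, x$prot_spec$name, x$n_features,
              x$training_seed))
  if (!is.null(x$metrics)) {
    cat(sprintf("  test MCC %.3f, accuracy %.3f\n",
                x$metrics$mcc, x$metrics$accuracy))
  }
  invisible(x)
}

#' Interaction probability for aptamer-protein pairs
#'
#' The mean positive-class probability over the forest's trees
#' (equivalently the fraction of trees voting positive), in `[0, 1]`.
#'
#' @param model An `api_classifier`.
#' @param aptamer Character vector of RNA sequences.
#' @param protein A single protein sequence, or one per aptamer.
#' @return Numeric vector of interaction probabilities.
#' @export
score_pairs <- function(model, aptamer, protein) {
  aptamer <- vapply(aptamer, normalize_nucleotides, "", USE.NAMES = FALSE)
  protein <- vapply(protein, normalize_protein, "", USE.NAMES = FALSE)
  data <- tibble::tibble(aptamer = aptamer, protein = protein)
  x <- encode_dataset(data, model$apt_spec, model$prot_spec)
  pr <- stats::predict(model$forest, data = as.data.frame(x),
                       num.threads = 1)$predictions
  unname(pr[, "positive"])
}

#' Bind a trained classifier to a target protein as an MCTS score function
#'
#' Pre-encodes the protein once and returns a vectorized scorer
#' `function(aptamers) -> probabilities`, the contract the tree search
#' consumes. Any function with that signature (e.g. a rigged test scorer)
#' satisfies the same contract.
#'
#' @param model An `api_classifier`.
#' @param protein Target protein sequence.
#' @return A function mapping a character vector of RNA sequences to
#'   interaction probabilities in `[0, 1]`.
#' @export
make_scorer <- function(model, protein) {
  protein <- normalize_protein(protein)
  pvec <- encode_sequence(protein, model$prot_spec)
  forest <- model$forest
  apt_spec <- model$apt_spec
  np <- length(pvec)
  function(aptamers) {
    amat <- t(vapply(aptamers, function(a) encode_sequence(a, apt_spec),
                     numeric(encoder_dim(apt_spec)), USE.NAMES = FALSE))
    x <- cbind(amat, matrix(pvec, nrow = length(aptamers), ncol = np,
                            byrow = TRUE))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    pr <- stats::predict(forest, data = as.data.frame(x),
                         num.threads = 1)$predictions
    unname(pr[, "positive"])
  }
}

#' Evaluate a classifier on a labelled dataset
#'
#' Scores every pair, thresholds at `threshold`, and returns the
#' confusion counts with all five metrics (see [compute_metrics()]).
#'
#' @param model An `api_classifier`.
#' @param data Labelled dataset (columns `aptamer`, `protein`, `label`).
#' @param threshold Positive-call threshold on the interaction
#'   probability (default 0.5).
#' @return One-row metrics tibble.
#' @export
evaluate_classifier <- function(model, data, threshold = 0.5) {
  if (nrow(data) == 0) {
    abort("empty evaluation dataset", class = "aptgen_empty_eval")
  }
  y <- normalize_labels(data$label)
  p <- score_pairs(model, data$aptamer, data$protein)
  pred <- p >= threshold
  compute_metrics(
    tp = sum(pred & y == "positive"),
    tn = sum(!pred & y == "negative"),
    fp = sum(pred & y == "negative"),
    fn = sum(!pred & y == "positive")
  )
}

#' Select the best interaction classifier by repeated training
#'
#' Trains `repeats` random-forest candidates per encoder combination,
#' each with a tree count drawn uniformly from `tree_range`, evaluates
#' every candidate on the held-out set, and returns the MCC-maximal
#' model. MCC ties are broken by the fewest trees (a slim forest is
#' cheaper inside the tree search), remaining ties by training order.
#' One run seed spawns one child seed per candidate, so a single integer
#' reproduces the whole selection.
#'
#' Candidates that fail to train are recorded in the leaderboard with
#' `NA` metrics and skipped; the run only errors if all candidates fail.
#'
#' @param train,test Labelled datasets (columns `aptamer`, `protein`,
#'   `label`).
#' @param grid Encoder combinations: a tibble like [encoder_grid()] (or a
#'   subset of it).
#' @param repeats Candidates per grid combination (default 2000).
#' @param tree_range Inclusive bounds for the uniform tree-count draw
#'   (default `c(30, 200)`).
#' @param seed Run seed.
#' @param threshold Classification threshold for evaluation.
#' @return An `api_selection`: list with `best` (an `api_classifier`
#'   carrying its test metrics) and `leaderboard` (one row per candidate).
#' @export
select_best_model <- function(train, test, grid = encoder_grid(),
                              repeats = 2000, tree_range = c(30, 200),
                              seed = 1, threshold = 0.5) {
  stopifnot(repeats >= 1, nrow(grid) >= 1, tree_range[1] <= tree_range[2])
  train <- dplyr::mutate(tibble::as_tibble(train),
                         aptamer = vapply(.data$aptamer, normalize_nucleotides, ""))
  test <- dplyr::mutate(tibble::as_tibble(test),
                        aptamer = vapply(.data$aptamer, normalize_nucleotides, ""))
  ytr <- normalize_labels(train$label)
  if (length(unique(ytr)) < 2) {
    abort("training data must contain both classes", class = "aptgen_untrainable")
  }
  yte <- normalize_labels(test$label)
  n_cand <- repeats * nrow(grid)
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_cand)

  freq <- table(ytr)
  cw <- setNames(as.numeric(sum(freq) / (2 * freq)), names(freq))
  rows <- vector("list", n_cand)
  best <- NULL  # list(model, mcc, n_trees, candidate)
  idx <- 0L
  for (g in seq_len(nrow(grid))) {
    apt_spec <- grid$apt_spec[[g]]
    prot_spec <- grid$prot_spec[[g]]
    # encode each dataset once per encoder combination
    enc <- tryCatch(list(
      xtr = encode_dataset(train, apt_spec, prot_spec),
      xte = encode_dataset(test, apt_spec, prot_spec)
    ), error = function(e) e)
    for (r in seq_len(repeats)) {
      idx <- idx + 1L
      cs <- child_seeds[idx]
      set.seed(cs)
      nt <- sample(seq(tree_range[1], tree_range[2]), 1L)
      res <- if (inherits(enc, "error")) enc else tryCatch({
        forest <- ranger::ranger(
          x = as.data.frame(enc$xtr), y = ytr, num.trees = nt,
          probability = TRUE, class.weights = cw, seed = cs, num.threads = 1)
        p <- stats::predict(forest, data = as.data.frame(enc$xte),
                            num.threads = 1)$predictions[, "positive"]
        pred <- p >= threshold
        met <- compute_metrics(
          tp = sum(pred & yte == "positive"), tn = sum(!pred & yte == "negative"),
          fp = sum(pred & yte == "negative"), fn = sum(!pred & yte == "positive"))
        list(forest = forest, metrics = met)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[idx]] <- tibble::tibble(
          candidate = idx, apt_encoder = grid$apt_encoder[g],
          prot_encoder = grid$prot_encoder[g], n_trees = nt, seed = cs,
          sensitivity = NA_real_, specificity = NA_real_,
          accuracy = NA_real_, youden_j = NA_real_, mcc = NA_real_,
          error = conditionMessage(res)
        )
      } else {
        met <- res$metrics
        rows[[idx]] <- tibble::tibble(
          candidate = idx, apt_encoder = grid$apt_encoder[g],
          prot_encoder = grid$prot_encoder[g], n_trees = nt, seed = cs,
          sensitivity = met$sensitivity, specificity = met$specificity,
          accuracy = met$accuracy, youden_j = met$youden_j, mcc = met$mcc,
          error = NA_character_
        )
        # keep only the incumbent: max MCC, then fewest trees, then order
        if (is.null(best) || met$mcc > best$mcc ||
            (met$mcc == best$mcc && nt < best$n_trees)) {
          model <- structure(
            list(forest = res$forest, apt_spec = apt_spec,
                 prot_spec = prot_spec, n_trees = nt, training_seed = cs,
                 balanced = TRUE, n_features = ncol(enc$xtr), metrics = met,
                 schema = "aptgen-model-v1"),
            class = "api_classifier")
          best <- list(model = model, mcc = met$mcc, n_trees = nt,
                       candidate = idx)
        }
      }
    }
  }
  leaderboard <- dplyr::bind_rows(rows)
  if (is.null(best)) {
    abort("all candidate models failed to train", class = "aptgen_untrainable")
  }
  structure(
    list(best = best$model, best_candidate = best$candidate,
         leaderboard = leaderboard,
         config = list(repeats = repeats, tree_range = tree_range,
                       seed = seed, threshold = threshold)),
    class = "api_selection"
  )
}

#' @export
print.api_selection <- function(x, ...) {
  lb <- x$leaderboard
  cat(sprintf("<api_selection> %d candidates (%d failed)\n",
              nrow(lb), sum(!is.na(lb$error))))
  cat(sprintf("  best: candidate %d, %s x %s, %d trees, MCC %.3f\n",
              x$best_candidate, x$best$apt_spec$name, x$best$prot_spec$name,
              x$best$n_trees, x$best$metrics$mcc))
  invisible(x)
}

#' Tidy the candidate leaderboard of a model selection run
#'
#' One row per trained candidate (encoder combination, tree count, test
#' metrics), mirroring the layout of a benchmark comparison table.
#'
#' @param x An `api_selection`.
#' @param ... Unused.
#' @return Tibble leaderboard.
#' @export
tidy.api_selection <- function(x, ...) x$leaderboard

#' One-row summary of a model selection run
#'
#' @param x An `api_selection`.
#' @param ... Unused.
#' @return One-row tibble describing the selected model.
#' @export
glance.api_selection <- function(x, ...) {
  m <- x$best$metrics
  tibble::tibble(
    n_candidates = nrow(x$leaderboard),
    n_failed = sum(!is.na(x$leaderboard$error)),
    apt_encoder = x$leaderboard$apt_encoder[x$best_candidate],
    prot_encoder = x$leaderboard$prot_encoder[x$best_candidate],
    n_trees = x$best$n_trees,
    sensitivity = m$sensitivity, specificity = m$specificity,
    accuracy = m$accuracy, youden_j = m$youden_j, mcc = m$mcc
  )
}

#' One-row summary of a trained classifier
#'
#' @param x An `api_classifier`.
#' @param ... Unused.
#' @return One-row tibble (encoders, tree count, test metrics if known).
#' @export
glance.api_classifier <- function(x, ...) {
  base <- tibble::tibble(
    apt_encoder = x$apt_spec$name, prot_encoder = x$prot_spec$name,
    n_trees = x$n_trees, n_features = x$n_features,
    training_seed = x$training_seed
  )
  if (!is.null(x$metrics)) {
    base <- dplyr::bind_cols(
      base,
      dplyr::select(x$metrics, "sensitivity", "specificity",
                    "accuracy", "youden_j", "mcc"))
  }
  base
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
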