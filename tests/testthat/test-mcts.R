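# UCT arithmetic, directional-base reconstruction, tree mechanics
# (selection / expansion / playout / backpropagation), and the
# round-level and full-run sampling contracts.

test_that("uct reproduces the selection formula and its limits", {
  expect_equal(uct(1, 1, 1, 12), 1)                       # ln(1) = 0
  expect_equal(uct(3, 2, 10, 12), 1.5 + 12 * sqrt(log(10) / 2))
  expect_equal(uct(0.9, 1, 5, 0), 0.9)                    # C = 0: mean only
  expect_identical(uct(0, 0, 5, 12), Inf)                 # unvisited preferred
  v <- uct(c(1, 0, 2), c(2, 0, 4), 10, 3)
  expect_identical(v[2], Inf)
  expect_equal(v[1], 0.5 + 3 * sqrt(log(10) / 2))
})

test_that("reconstruction follows the directional-base rule", {
  expect_identical(reconstruct("GAU", c("_U", "_C", "A_", "G_")), "GAGAUUC")
  expect_equal(nchar(reconstruct("GAU", c("_U", "_C", "A_", "G_"))), 7)
  expect_identical(reconstruct("", "_A"), "A")
  expect_identical(reconstruct("", "A_"), "A")
  expect_identical(reconstruct("AC"), "AC")
  expect_error(reconstruct("AC", "X_"), class = "aptgen_bad_base")
  set.seed(201)
  for (i in 1:50) {
    core <- random_rna(sample(0:6, 1))
    labs <- sample(directional_bases(), 12, replace = TRUE)
    got <- reconstruct(core, labs)
    expect_identical(got, oracle_deque(core, labs))
    expect_equal(nchar(got), nchar(core) + 12)
    expect_identical(sort(strsplit(got, "")[[1]]),
                     sort(c(strsplit(core, "")[[1]], substr(gsub("_", "", labs), 1, 1))))
  }
})

test_that("the directional-base alphabet has exactly 8 labels in both sides", {
  db <- directional_bases()
  expect_length(db, 8)
  expect_length(unique(db), 8)
  expect_equal(sum(endsWith(db, "_")), 4)   # prepend forms
  expect_equal(sum(startsWith(db, "_")), 4) # append forms
})

test_that("selection descends by brute-force UCT argmax at every level", {
  build <- function(depth) {
    node <- aptgen:::mcts_node()
    node$nkids <- 8L
    node$kn <- sample(1:50, 8)
    node$ks <- runif(8) * node$kn
    node$kids <- lapply(1:8, function(i) {
      if (depth > 1) build(depth - 1) else aptgen:::mcts_node()
    })
    node
  }
  set.seed(202)
  for (rep in 1:20) {
    root <- build(3)
    root$n <- sum(root$kn)
    c_explore <- sample(c(0, 1, 12), 1)
    sel <- aptgen:::mcts_select(root, c_explore, limit = 3)
    node <- root; n_parent <- root$n
    for (step in sel$path) {
      u <- uct(node$ks, node$kn, n_parent, c_explore)
      expect_equal(u[step], max(u))   # per-level exhaustive argmax
      n_parent <- node$kn[step]
      node <- node$kids[[step]]
    }
    expect_equal(sel$depth, 3)
  }
  # a childless root yields an empty path
  lone <- aptgen:::mcts_node()
  expect_length(aptgen:::mcts_select(lone, 12, limit = 5)$path, 0)
})

test_that("expansion instantiates missing labels uniformly", {
  node <- aptgen:::mcts_node()
  for (i in 1:7) aptgen:::mcts_expand(node)
  missing <- which(vapply(node$kids, is.null, TRUE))
  expect_length(missing, 1)
  expect_equal(aptgen:::mcts_expand(node), missing)  # forced choice
  expect_equal(node$nkids, 8L)

  set.seed(203)
  picks <- replicate(8000, aptgen:::mcts_expand(aptgen:::mcts_node()))
  counts <- tabulate(picks, 8)
  # chi-square against uniform on 7 df; 24.32 is the 0.999 quantile
  chisq <- sum((counts - 1000)^2 / 1000)
  expect_lt(chisq, 24.32)
})

test_that("random playout has the right length and uniform marginals", {
  expect_length(aptgen:::mcts_simulate(7, 7), 0)
  expect_length(aptgen:::mcts_simulate(2, 7), 5)
  set.seed(204)
  draws <- unlist(replicate(2000, aptgen:::mcts_simulate(0, 4), simplify = FALSE))
  counts <- tabulate(draws, 8)
  chisq <- sum((counts - length(draws) / 8)^2 / (length(draws) / 8))
  expect_lt(chisq, 24.32)
})

test_that("backpropagation adds the score along the whole path", {
  root <- aptgen:::mcts_node()
  i <- aptgen:::mcts_expand(root)
  aptgen:::mcts_backprop(root, i, 0.7)
  expect_equal(root$n, 1)
  expect_equal(root$ks[i], 0.7)
  expect_equal(root$kn[i], 1)
  for (k in 1:9) aptgen:::mcts_backprop(root, i, 0.5)
  expect_equal(root$ks[i], 0.7 + 9 * 0.5)  # additivity
  expect_equal(root$kn[i], 10)
})

test_that("a round emits exactly M full-length candidates and conserves visits", {
  rr <- run_round("", function(s) 0.5, length_target = 6, m_iter = 10)
  expect_equal(nrow(rr$candidates), 10)
  expect_equal(rr$root_visits, 10)
  expect_true(all(nchar(rr$candidates$sequence) == 6))
  expect_equal(sum(rr$root_children$n), 10)  # children account for all visits

  # last-round degeneracy: one position left
  rr1 <- run_round("ACGUA", function(s) 0.5, length_target = 6, m_iter = 20)
  expect_true(all(nchar(rr1$candidates$sequence) == 6))
  diffs <- vapply(rr1$candidates$sequence, function(s) {
    s %in% vapply(directional_bases(), function(b) reconstruct("ACGUA", b), "")
  }, TRUE)
  expect_true(all(diffs))

  expect_error(run_round("", function(s) 0.5, 6, m_iter = 0),
               class = "aptgen_bad_config")
  expect_error(run_round("ACGUAC", function(s) 0.5, 6, m_iter = 5),
               class = "aptgen_bad_config")
  expect_error(run_round("", function(s) 2, 4, m_iter = 3),
               class = "aptgen_bad_score")
})

test_that("node mean scores stay inside [0,1] for probability scorers", {
  set.seed(205)
  scorer <- function(s) 1 / (1 + exp(-(nchar(gsub("[^G]", "", s)) - 2)))
  rr <- run_round("", scorer, length_target = 5, m_iter = 300)
  means <- rr$root_children$mean[rr$root_children$n > 0]
  expect_true(all(means >= 0 & means <= 1))
  expect_true(all(rr$candidates$score >= 0 & rr$candidates$score <= 1))
})

test_that("a motif-rigged scorer drives the committed base to the motif letter", {
  # scorer rewards sequences starting with G: prepend-G must win the round
  set.seed(206)
  scorer <- function(s) if (startsWith(s, "G")) 1 else 0
  rr <- run_round("", scorer, length_target = 4, m_iter = 400)
  expect_identical(rr$best, "G_")
  # exhaustive audit: G_ has the top mean among the root children
  rc <- rr$root_children
  expect_equal(which.max(ifelse(rc$n > 0, rc$mean, -Inf)),
               match("G_", rc$label))

  # exploitation-only sanity at C = 0: at the last position (no playout
  # noise) the preferred letter/side must be committed for every seed
  for (s in 1:5) {
    set.seed(s)
    rr0 <- run_round("AAA", scorer, length_target = 4, m_iter = 50,
                     c_explore = 0)
    expect_identical(rr0$best, "G_")
    set.seed(s)
    rr1 <- run_round("AAA", function(x) if (endsWith(x, "C")) 1 else 0,
                     length_target = 4, m_iter = 50, c_explore = 0)
    expect_identical(rr1$best, "_C")
  }
})

test_that("a full run yields N*M candidates of length N, reproducibly", {
  sc <- make_rigged_scorer("GGA")
  out <- generate_aptamers(sc, aptamer_length = 4, m_per_round = 50, seed = 9)
  expect_equal(nrow(out), 200)
  expect_true(all(nchar(out$sequence) == 4))
  expect_lte(length(unique(out$sequence)), 4^4)
  out2 <- generate_aptamers(sc, aptamer_length = 4, m_per_round = 50, seed = 9)
  expect_identical(out$sequence, out2$sequence)
  expect_identical(out$score, out2$score)
  committed <- attr(out, "committed")
  expect_equal(nrow(committed), 4)
  expect_equal(nchar(committed$core[4]), 4)

  # two scorers: independent searches, top-5 each reported
  two <- generate_aptamers(list(a = sc, b = make_rigged_scorer("CCU")),
                           aptamer_length = 5, m_per_round = 30, seed = 9)
  expect_equal(nrow(two), 2 * 5 * 30)
  tops <- lapply(split(two, two$scorer_id), function(g) {
    top_candidates(dedup_candidates(g), k = 5)
  })
  # per scorer: min(5, number of distinct structures) candidates
  for (id in names(tops)) {
    g <- two[two$scorer_id == id, ]
    n_struct <- length(unique(fold_rna(unique(g$sequence))))
    expect_equal(nrow(tops[[id]]), min(5, n_struct))
  }
})

test_that("sampler converges on a planted motif", {
  sc <- make_rigged_scorer("GGA")
  hits <- vapply(1:2, function(s) {
    out <- generate_aptamers(sc, aptamer_length = 10, m_per_round = 400, seed = s)
    top <- top_candidates(dedup_candidates(out), k = 10)
    mean(grepl("GGA", top$sequence))
  }, numeric(1))
  expect_true(all(hits >= 0.9))
})
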