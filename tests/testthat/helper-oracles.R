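# Independent brute-force oracles and small fixture builders shared by
# the test files. These deliberately re-derive quantities by the most
# literal route available (sliding windows, direct summation, exhaustive
# enumeration) and never call the package code paths they check.

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(protein_alphabet(), len, replace = TRUE), collapse = "")
}

# literal sliding-window k-mer counter
oracle_kmer_freq <- function(seq, k, alphabet) {
  units <- sort(apply(expand.grid(rep(list(alphabet), k)), 1,
                      function(r) paste(rev(r), collapse = "")))
  counts <- setNames(numeric(length(units)), units)
  for (i in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    counts[w] <- counts[w] + 1
  }
  counts / (nchar(seq) - k + 1)
}

# direct double-loop covariance sums over a property matrix
oracle_auto_cov <- function(seq, unit_size, table, max_lag) {
  pm <- as.matrix(table[setdiff(names(table), "unit")])
  rownames(pm) <- table$unit
  starts <- seq_len(nchar(seq) - unit_size + 1)
  units <- substring(seq, starts, starts + unit_size - 1)
  Lp <- length(units)
  out <- c()
  for (p in colnames(pm)) {
    v <- pm[units, p]
    vbar <- mean(v)
    for (l in seq_len(max_lag)) {
      acc <- 0
      for (i in seq_len(Lp - l)) acc <- acc + (v[i] - vbar) * (v[i + l] - vbar)
      out <- c(out, acc / (Lp - l))
    }
  }
  unname(out)
}

oracle_cross_cov <- function(seq, unit_size, table, max_lag) {
  pm <- as.matrix(table[setdiff(names(table), "unit")])
  rownames(pm) <- table$unit
  starts <- seq_len(nchar(seq) - unit_size + 1)
  units <- substring(seq, starts, starts + unit_size - 1)
  Lp <- length(units)
  out <- c()
  for (p in colnames(pm)) {
    for (q in colnames(pm)) {
      if (p == q) next
      vp <- pm[units, p] - mean(pm[units, p])
      vq <- pm[units, q] - mean(pm[units, q])
      for (l in seq_len(max_lag)) {
        acc <- 0
        for (i in seq_len(Lp - l)) acc <- acc + vp[i] * vq[i + l]
        out <- c(out, acc / (Lp - l))
      }
    }
  }
  unname(out)
}

# literal class-triad counter with min-max normalization
oracle_triad <- function(seq, classes) {
  nc <- max(classes)
  res <- strsplit(seq, "")[[1]]
  counts <- numeric(nc^3)
  for (i in seq_len(length(res) - 2)) {
    c1 <- classes[[res[i]]]; c2 <- classes[[res[i + 1]]]; c3 <- classes[[res[i + 2]]]
    idx <- (c1 - 1) * nc * nc + (c2 - 1) * nc + c3
    counts[idx] <- counts[idx] + 1
  }
  (counts - min(counts)) / max(counts)
}

# positional-scan CTD oracle for one attribute grouping
oracle_ctd_attr <- function(seq, residues_by_group) {
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  g <- integer(L)
  for (k in 1:3) g[res %in% strsplit(residues_by_group[k], "")[[1]]] <- k
  comp <- sapply(1:3, function(k) sum(g == k) / L)
  trans <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
    n <- 0
    for (i in seq_len(L - 1)) {
      if ((g[i] == pr[1] && g[i + 1] == pr[2]) ||
          (g[i] == pr[2] && g[i + 1] == pr[1])) n <- n + 1
    }
    n / (L - 1)
  })
  dist <- c()
  for (k in 1:3) {
    occ <- which(g == k)
    n <- length(occ)
    d <- if (n == 0) rep(0, 5) else
      c(occ[1], occ[ceiling(0.25 * n)], occ[ceiling(0.5 * n)],
        occ[ceiling(0.75 * n)], occ[n]) / L
    dist <- c(dist, d)
  }
  c(comp, trans, dist)
}

# double-ended-queue simulation of directional-base reconstruction
oracle_deque <- function(core, labels) {
  dq <- strsplit(core, "")[[1]]
  for (lab in labels) {
    if (substr(lab, 2, 2) == "_") {
      dq <- c(substr(lab, 1, 1), dq)        # prepend form "X_"
    } else {
      dq <- c(dq, substr(lab, 2, 2))        # append form "_X"
    }
  }
  paste(dq, collapse = "")
}

# exhaustive enumeration of nested loop>=3 structures; returns the
# maximum number of pairs (no memoization: literally tries everything)
oracle_max_pairs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i + 1, j)
    for (k in (i + 4):j) {
      if (pairable(ch[i], ch[k])) {
        inner <- if (k - i > 4) rec(i + 1, k - 1) else 0
        rest <- if (k < j) rec(k + 1, j) else 0
        best <- max(best, 1 + inner + rest)
      }
    }
    best
  }
  rec(1, length(ch))
}

# check a dot-bracket string: balanced, properly nested, loop >= 3,
# and only admissible pairs; returns the number of pairs
check_dot_bracket <- function(seq, db) {
  expect_equal(nchar(db), nchar(seq))
  ch <- strsplit(db, "")[[1]]
  sq <- strsplit(seq, "")[[1]]
  stack <- integer(0)
  npairs <- 0
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      expect_gt(length(stack), 0)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      expect_gte(i - j, 4)  # at least 3 unpaired bases enclosed
      expect_true(paste0(sq[j], sq[i]) %in%
                    c("AU", "UA", "GC", "CG", "GU", "UG"))
      npairs <- npairs + 1
    }
  }
  expect_length(stack, 0)
  npairs
}

# small shared-pool train/test pair for classifier tests; short
# aptamers so the planted motif is recoverable at unit-test scale
learnable_datasets <- function(seed, noise_rate = 0,
                               n_pos = 120, n_neg = 360,
                               test_pos = 60, test_neg = 180) {
  cfg <- synthetic_config(n_pos = n_pos, n_neg = n_neg, n_proteins = 4,
                          aptamer_length_range = c(20, 30),
                          protein_length_range = c(50, 120),
                          noise_rate = noise_rate, seed = seed)
  train <- generate_api_dataset(cfg)
  tcfg <- cfg
  tcfg$n_pos <- test_pos; tcfg$n_neg <- test_neg
  tcfg$noise_rate <- 0; tcfg$seed <- seed + 1000
  test <- generate_api_dataset(tcfg, proteins = attr(train, "proteins"))
  list(train = train, test = test, cfg = cfg)
}

small_grid <- function(apt = "PseKNC(k=3)", prot = "AAC") {
  g <- encoder_grid()
  g[g$apt_encoder == apt & g$prot_encoder == prot, ]
}
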