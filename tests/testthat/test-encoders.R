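# Encoder correctness against literal brute-force recomputation, plus
# the fixed-dimension, normalization and purity contracts every encoder
# must satisfy.

test_that("k-mer composition equals the sliding-window oracle", {
  expect_equal(unname(kmer_frequencies("AAAA", 1, "rna")), c(1, 0, 0, 0))
  expect_equal(unname(kmer_frequencies("ACGU", 1, "rna")), rep(0.25, 4))
  set.seed(101)
  for (i in 1:40) {
    s <- random_rna(sample(10:60, 1))
    k <- sample(1:3, 1)
    got <- kmer_frequencies(s, k, "rna")
    ora <- oracle_kmer_freq(s, k, rna_alphabet())
    expect_equal(got[names(ora)], ora)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
  for (i in 1:40) {
    s <- random_protein(sample(20:60, 1))
    k <- sample(1:3, 1)
    got <- kmer_frequencies(s, k, "protein")
    ora <- oracle_kmer_freq(s, k, protein_alphabet())
    expect_equal(got[names(ora)], ora)
  }
  expect_error(kmer_frequencies("AC", 3, "rna"), class = "aptgen_too_short")
})

test_that("auto- and cross-covariance match direct summation", {
  tab2 <- property_table("rna_dinucleotide")
  tab3 <- property_table("rna_trinucleotide")
  # constant property signal: a homopolymer has zero deviations
  expect_equal(unname(auto_covariance("AAAAAAAA", 2, tab2, 2)), rep(0, 6))
  expect_equal(unname(cross_covariance("AAAAAAAA", 2, tab2, 2)), rep(0, 12))
  set.seed(102)
  for (i in 1:30) {
    s <- random_rna(sample(12:50, 1))
    u <- sample(2:3, 1)
    tab <- if (u == 2) tab2 else tab3
    lag <- sample(1:3, 1)
    expect_equal(unname(auto_covariance(s, u, tab, lag)),
                 oracle_auto_cov(s, u, tab, lag))
    expect_equal(unname(cross_covariance(s, u, tab, lag)),
                 oracle_cross_cov(s, u, tab, lag))
  }
  expect_error(auto_covariance("ACG", 2, tab2, 2), class = "aptgen_too_short")
})

test_that("concatenated covariance encoders stack auto then cross blocks", {
  s <- random_rna(30)
  dacc <- encode_sequence(s, encoder_spec("DACC"))
  dac <- encode_sequence(s, encoder_spec("DAC"))
  dcc <- encode_sequence(s, encoder_spec("DCC"))
  expect_equal(unname(dacc), unname(c(dac, dcc)))
  expect_equal(length(dacc), length(dac) + length(dcc))
})

test_that("PseKNC reduces to k-mer composition at w = 0 and matches the direct formula", {
  s <- "ACGUAC"
  p0 <- pseknc(s, k = 2, lambda = 1, w = 0)
  expect_equal(p0[1:16], kmer_frequencies(s, 2, "rna"))
  expect_equal(unname(p0[17]), 0)
  expect_length(pseknc(random_rna(20), k = 3, lambda = 2), 66)

  # direct evaluation of theta_1 and the shared normalizer on a 6-mer
  tab <- property_table("rna_dinucleotide")
  pm <- as.matrix(tab[-1]); rownames(pm) <- tab$unit
  units <- substring(s, 1:5, 2:6)
  th1 <- mean(sapply(1:4, function(i) {
    mean((pm[units[i], ] - pm[units[i + 1], ])^2)
  }))
  f <- oracle_kmer_freq(s, 2, rna_alphabet())
  w <- 0.05
  expected <- c(f / (1 + w * th1), w * th1 / (1 + w * th1))
  got <- pseknc(s, k = 2, lambda = 1, w = w)
  expect_equal(unname(got), unname(expected))
  expect_equal(sum(got), 1, tolerance = 1e-9)
  expect_error(pseknc("ACG", k = 3, lambda = 2), class = "aptgen_too_short")
})

test_that("PseAAC reduces to padded AAC at w = 0 and matches the direct formula", {
  s <- "MKVLA"
  p0 <- pseaac(s, lambda = 1, w = 0)
  expect_equal(p0[1:20], kmer_frequencies(s, 1, "protein"))
  expect_equal(unname(p0[21]), 0)
  expect_length(pseaac(random_protein(40), lambda = 10), 30)

  tab <- property_table("amino_acid")
  pm <- as.matrix(tab[-1]); rownames(pm) <- tab$unit
  res <- strsplit(s, "")[[1]]
  th1 <- mean(sapply(1:4, function(i) mean((pm[res[i], ] - pm[res[i + 1], ])^2)))
  f <- oracle_kmer_freq(s, 1, protein_alphabet())
  w <- 0.05
  expected <- c(f / (1 + w * th1), w * th1 / (1 + w * th1))
  expect_equal(unname(pseaac(s, lambda = 1, w = w)), unname(expected))
  expect_error(pseaac("MKV", lambda = 5), class = "aptgen_too_short")
})

test_that("conjoint triads match the brute-force counter and its normalization", {
  expect_length(conjoint_triad(random_protein(40), "protein"), 343)
  expect_length(conjoint_triad(random_rna(40), "rna"), 64)
  # one repeated class: exactly one nonzero triad
  expect_equal(sum(conjoint_triad("AGVAGV", "protein") > 0), 1)
  set.seed(103)
  for (i in 1:30) {
    s <- random_protein(40)
    got <- conjoint_triad(s, "protein")
    expect_equal(unname(got), oracle_triad(s, triad_classes("protein")))
    expect_true(all(got >= 0 & got <= 1))
    expect_equal(max(got), 1)  # min count 0 at this length, so max entry is 1
  }
  for (i in 1:10) {
    s <- random_rna(25)
    expect_equal(unname(conjoint_triad(s, "rna")),
                 oracle_triad(s, triad_classes("rna")))
  }
})

test_that("CTD matches a positional-scan oracle attribute by attribute", {
  groups <- ctd_groups()
  attrs <- unique(groups$attribute)
  set.seed(104)
  for (i in 1:20) {
    s <- random_protein(50)
    got <- ctd_features(s)
    expect_length(got, 147)
    for (a in seq_along(attrs)) {
      block <- got[((a - 1) * 21 + 1):(a * 21)]
      ga <- groups[groups$attribute == attrs[a], ]
      expect_equal(unname(block), oracle_ctd_attr(s, ga$residues),
                   info = attrs[a])
      expect_equal(sum(block[1:3]), 1, tolerance = 1e-9)  # composition sums to 1
    }
  }
  # single-group homopolymer: its transitions 0, first occurrence at 1/L
  h <- ctd_features("RRRRR")
  expect_equal(unname(h[4:6]), c(0, 0, 0))       # hydrophobicity transitions
  expect_equal(unname(h[7]), 1 / 5)              # group-1 first occurrence
})

test_that("encoders are pure and fixed-dimension across sequence lengths", {
  grid <- encoder_grid()
  specs <- c(unique(grid$apt_spec), unique(grid$prot_spec))
  set.seed(105)
  for (spec in specs) {
    mk <- if (spec$alphabet == "rna") random_rna else random_protein
    s1 <- mk(25); s2 <- mk(60)
    v1 <- encode_sequence(s1, spec)
    v2 <- encode_sequence(s2, spec)
    expect_equal(length(v1), encoder_dim(spec), info = spec$name)
    expect_equal(length(v2), encoder_dim(spec), info = spec$name)
    expect_identical(v1, encode_sequence(s1, spec))  # bit-identical rerun
    expect_true(all(is.finite(v1)))
  }
})

test_that("declared dimensions match their closed forms", {
  expect_equal(encoder_dim(encoder_spec("AAC")), 20)
  expect_equal(encoder_dim(encoder_spec("DPC")), 400)
  expect_equal(encoder_dim(encoder_spec("TPC")), 8000)
  expect_equal(encoder_dim(encoder_spec("CTD")), 147)
  expect_equal(encoder_dim(encoder_spec("iCTF", alphabet = "protein")), 343)
  expect_equal(encoder_dim(encoder_spec("iCTF", alphabet = "rna")), 64)
  expect_equal(encoder_dim(encoder_spec("PseKNC", k = 3, lambda = 2)), 66)
  expect_equal(encoder_dim(encoder_spec("PseKNC", k = 2, lambda = 5)), 21)
  expect_equal(encoder_dim(encoder_spec("PseAAC", lambda = 10)), 30)
  # cross-covariance dimension formula: P(P-1) pairs x lags
  tab <- property_table("rna_dinucleotide")
  np <- ncol(tab) - 1
  expect_equal(encoder_dim(encoder_spec("DCC", lag = 2)), np * (np - 1) * 2)
})

test_that("pair encoding is the concatenation of its two blocks", {
  apt_spec <- encoder_spec("PseKNC", k = 3)
  prot_spec <- encoder_spec("CTD")
  set.seed(106)
  a <- random_rna(30); p <- random_protein(80)
  pair <- encode_pair(a, p, apt_spec, prot_spec)
  expect_length(pair, encoder_dim(apt_spec) + encoder_dim(prot_spec))
  expect_equal(unname(pair[1:66]), unname(encode_sequence(a, apt_spec)))
  expect_equal(unname(pair[67:213]), unname(encode_sequence(p, prot_spec)))
  expect_identical(pair, encode_pair(a, p, apt_spec, prot_spec))
})

test_that("the full encoder grid enumerates all 54 combinations", {
  grid <- encoder_grid()
  expect_equal(nrow(grid), 54)
  expect_equal(length(unique(grid$apt_encoder)), 9)
  expect_equal(length(unique(grid$prot_encoder)), 6)
  expect_true(all(vapply(grid$apt_spec, function(s) s$alphabet == "rna", TRUE)))
  expect_true(all(vapply(grid$prot_spec, function(s) s$alphabet == "protein", TRUE)))
})

test_that("property tables are complete and standardized", {
  for (id in c("rna_dinucleotide", "rna_trinucleotide", "amino_acid")) {
    tab <- property_table(id)
    m <- as.matrix(tab[-1])
    expect_equal(unname(colMeans(m)), rep(0, ncol(m)), tolerance = 1e-12)
    expect_equal(unname(apply(m, 2, sd)), rep(1, ncol(m)), tolerance = 1e-12)
  }
  expect_equal(nrow(property_table("rna_dinucleotide")), 16)
  expect_equal(nrow(property_table("rna_trinucleotide")), 64)
  expect_equal(nrow(property_table("amino_acid")), 20)
  groups <- ctd_groups()
  for (a in unique(groups$attribute)) {
    res <- paste(groups$residues[groups$attribute == a], collapse = "")
    expect_setequal(strsplit(res, "")[[1]], protein_alphabet())
  }
})
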