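# aptgen

Candidate RNA aptamer generation for a target protein, by coupling a
random-forest aptamer–protein interaction (API) classifier with an
iterative forward Monte Carlo tree search (MCTS) over a
directional-base sequence tree.

## The problem

Aptamers are short single-stranded oligonucleotides that fold into
three-dimensional shapes binding a specific target protein. Finding
them in vitro (SELEX) is slow and expensive, so a useful in silico
shortcut is: train a classifier that scores an (aptamer, protein) pair
with an interaction probability, then *search* sequence space for
aptamers of a chosen length `N` that maximize that score for a given
target. Exhaustive search over `4^N` sequences is hopeless; `aptgen`
organizes the search as `N` rounds of MCTS, each round committing one
base.

`aptgen` is aimed at computational biologists who want a seeded,
scriptable candidate generator: everything runs from a single integer
seed, and a built-in synthetic benchmark generator with a plantable
motif interaction rule makes the whole pipeline testable offline.

## The method

**Score function.** A random forest over fixed-length pair encodings.
Nine aptamer encoder families (dinucleotide/trinucleotide auto-, cross-
and combined covariance — DAC, DCC, DACC, TAC, TCC, TACC; PseKNC with
k = 2, 3; conjoint triads) and six protein families (AAC, DPC, TPC,
PseAAC, CTD, conjoint triads) give a 9 × 6 = 54-combination grid. The
classifier is selected by training many candidates (2000 by default),
each with a tree count drawn uniformly from [30, 200], and keeping the
one with the best held-out Matthews correlation coefficient (MCC);
ties go to the fewest trees, since the score function is called tens
of thousands of times during the search.

**Search.** The tree's nodes are *directional bases* — `A_`, `C_`,
`G_`, `U_` (prepend) and `_A`, `_C`, `_G`, `_U` (append) — so a path
of depth `N` spells out a full sequence from both ends; e.g. core
`GAU` extended with `[_U, _C, A_, G_]` builds
`GAU → GAUU → GAUUC → AGAUUC → GAGAUUC`. Each of `M` iterations
(default 5000) per round descends by the UCT rule

    UCT(i) = s_i / n_i + C * sqrt(ln(N_parent) / n_i),    C = 12

expands a random unvisited child, completes the sequence by a random
playout, scores it with the classifier, and backs the score up the
path. After `M` iterations the root child with the best mean score is
committed, and the next round starts one position deeper. A full run
therefore scores `N * M` candidates, which are then deduplicated by
predicted secondary structure (identical dot-bracket strings keep only
their best-scoring sequence) and ranked by score. Folding uses a
built-in Nussinov-style maximum base-pairing program (AU/GC/GU pairs,
hairpin loops ≥ 3); an RNAfold-compatible external backend is opt-in.

## Worked example

Generate a small synthetic benchmark, select a classifier, and sample
candidates for one of its target proteins:

```r
library(aptgen)
library(dplyr)

cfg <- synthetic_config(n_pos = 60, n_neg = 180, n_proteins = 4,
                        aptamer_length_range = c(20, 30),
                        protein_length_range = c(50, 120),
                        noise_rate = 0, seed = 42)
paths <- cmd_synth("demo", cfg)
train <- read_api_dataset(paths$train)
test  <- read_api_dataset(paths$test)

g <- encoder_grid()   # all 54 combinations; subset for a quick run
sel <- select_best_model(train, test,
         grid = filter(g, apt_encoder == "PseKNC(k=3)", prot_encoder == "AAC"),
         repeats = 10, seed = 1)
sel
#> <api_selection> 10 candidates (0 failed)
#>   best: candidate 1, PseKNC x AAC, 41 trees, MCC 0.463

target <- attr(generate_api_dataset(cfg), "proteins")[1]
scorer <- make_scorer(sel$best, target)
out <- generate_aptamers(scorer, aptamer_length = 20, m_per_round = 100, seed = 7)
top_candidates(dedup_candidates(out), k = 5)[, c("rank", "sequence", "score", "dot_bracket")]
#> # A tibble: 5 × 4
#>    rank sequence             score dot_bracket
#>   <int> <chr>                <dbl> <chr>
#> 1     1 UUUAGUUGGCGCGUAGCGAA 0.784 (((.((((...)).).))))
#> 2     2 AUUAGUUGGCGCGUAGCGAA 0.778 .((.((((...)).).))).
#> 3     3 GUUAGUUGGCGCGUAGCGAA 0.778 ((((((....)).))))...
#> 4     4 AUUUAGUUGGCGCGUAGCGA 0.760 ((...))(..(((...))))
#> 5     5 CUUUAGUUGGCGCGUAGCGA 0.760 ((((.((....))).)).).
```

Each row is one candidate aptamer: its interaction score is the
fraction of forest trees voting "binds" for this (aptamer, target)
pair, and `dot_bracket` is its predicted secondary structure (the
deduplication key). Scores well above the random-sequence baseline
(here ≈ 0.4) indicate the search concentrated on what the classifier
considers binders.

The same pipeline is scriptable from a shell via
`inst/cli/aptgen.R` (`synth`, `train`, `evaluate`, `generate`
subcommands), which writes TSV/FASTA/Vienna outputs plus a JSON
manifest (resolved config, seed, input checksums) next to every
artifact.

## Scope

`aptgen` generates and ranks candidate sequences; it does not dock
them. Downstream validation of binding (3D structure prediction,
docking simulation) is deliberately out of scope.
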