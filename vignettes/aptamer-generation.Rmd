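---
title: "Generating candidate aptamers with a classifier-guided tree search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating candidate aptamers with a classifier-guided tree search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what its tests do and do not
establish. The pipeline has four stages: pair encoding, classifier
training and selection, the tree search itself, and structure-based
post-processing; a synthetic benchmark generator closes the loop so
everything is testable offline.

## Sequence encodings

Machine-learning score functions need fixed-length inputs, while
aptamers and proteins vary in length. Every encoder here maps a
sequence to a vector whose dimension depends only on the encoder
configuration:

* **k-mer composition** (`kmer_frequencies()`): relative frequencies of
  overlapping k-mers in fixed lexicographic order; AAC/DPC/TPC are the
  protein cases k = 1, 2, 3 (dimensions 20/400/8000).
* **Covariance families** (`auto_covariance()`, `cross_covariance()`):
  the sequence is read as a series of dinucleotide or trinucleotide
  units, each unit mapped to standardized physicochemical property
  values; auto-covariance correlates one property with itself at lags
  1..`lag`, cross-covariance correlates ordered property pairs. DACC and
  TACC concatenate the two blocks. The sequence mean is subtracted and
  the divisor is the number of summed terms.
* **PseKNC / PseAAC** (`pseknc()`, `pseaac()`): composition augmented
  with `lambda` sequence-order correlation factors; factor `theta_j`
  averages the squared property distance between units `j` apart, and
  both blocks share the normalizer `sum(f) + w * sum(theta)` so the
  vector sums to one.
* **Conjoint triads** (`conjoint_triad()`): residues are mapped to
  physicochemical classes (the canonical 7-class amino-acid partition;
  each RNA base its own class), class triples are counted, and counts
  are min–max normalized as `(f - f_min) / f_max`.
* **CTD** (`ctd_features()`): for seven attribute groupings of the
  amino acids into three groups each — composition, cross-group
  transition frequencies, and the positions (as fractions of the
  length) of each group's 1st/25%/50%/75%/100% occurrence; 147 values.

**Property tables.** The covariance and pseudo-composition encoders
need per-unit numeric scales, and no single canonical set exists for
RNA k-mers. The shipped tables are therefore constructed and
documented rather than copied: each k-mer inherits the mean of three
mononucleotide scales (Watson–Crick hydrogen-bond count, purine
indicator, nucleoside monophosphate mass) over its bases, and all
properties are standardized to mean 0 / variance 1 across units before
use — the scale-free form the correlation terms require. PseAAC uses
the classic triple (Kyte–Doolittle hydropathy, Hopp–Woods
hydrophilicity, side-chain mass). Tables are plain TSV under
`inst/extdata/` and can be replaced by a file in the same layout; a
model archive records which table id it was trained with, and unit
order is fixed lexicographic so archives are portable.

Defaults where a convention was needed: covariance `lag = 2`, PseKNC
`lambda = 2`, PseAAC `lambda = 10`, weight `w = 0.05` — small enough
that the composition block dominates, conventional for these
descriptor families, and all configurable per `encoder_spec()`.
Ambiguous residues (N, X, …) are rejected with their position rather
than imputed: silently imputing changes every downstream frequency.

## The interaction classifier

`train_forest()` fits a probability forest (`ranger`) on concatenated
pair encodings. Interaction benchmarks are imbalanced (roughly 1:3
positive:negative), so class weights inversely proportional to class
frequencies are applied by default; this is the standard "balanced"
reading of automatic weight adjustment, and the forest's remaining
hyperparameters stay at the underlying library's defaults. The
interaction score of a pair is the mean positive-class probability
across trees — equivalently the fraction of trees voting positive —
and classification for metric purposes thresholds at 0.5.

`select_best_model()` implements the selection protocol: `repeats`
candidates per encoder combination (2000 by default), each with a tree
count drawn uniformly from [30, 200], evaluated on a held-out set, the
MCC-maximal model kept. MCC is the natural criterion under class
imbalance. Ties are broken toward fewer trees — the selected model is
called once per search iteration, so a slim forest directly buys
search throughput — and then toward training order. One run seed
spawns one child seed per candidate (covering both the tree-count draw
and the forest itself), so a single integer reproduces an entire
selection run. Metrics with zero denominators are reported as 0 with a
`degenerate` flag instead of erroring: a degenerate candidate (e.g.
one that never predicts positive) must lose the selection, not abort
it. The MCC denominator is computed as a product of square roots to
avoid integer overflow, and clamped to [-1, 1] against last-ulp
drift.

## The tree search

Round `r` of `N` searches a tree of depth `N - |core|` whose edges are
the eight directional bases. Choices that were genuinely open:

* **UCT form.** The selection rule is the standard
  `s/n + C sqrt(ln N_parent / n)` with `C = 12`. Unvisited children
  score `+Inf`, so every instantiated child is tried once before any
  is re-exploited.
* **Committed base.** "Best root child" is read as highest *mean*
  backed-up score `s/n`, not highest cumulative `s` — cumulative score
  confounds quality with visit count under UCT. Ties break toward the
  larger visit count (better-estimated mean), then the fixed label
  order. This reading is a known divergence risk against
  implementations that commit by raw score or visit count; with `M`
  in the thousands the three criteria almost always agree.
* **First-level redundancy.** On an empty core, prepending and
  appending the same base yield the same one-letter sequence. The
  8-way branching is kept anyway (no collapsing to 4): the redundancy
  is confined to round one and collapsing would complicate the
  uniform node type.
* **One candidate per iteration.** Each iteration contributes exactly
  one full-length candidate — the reconstruction of its
  selection + expansion + playout path — giving exactly `N * M` raw
  candidates per run. Truncated selection-only paths are not
  additionally collected.
* **Score caching.** Identical playouts recur, so scores are memoized
  per sequence string within a run. This changes runtime only; every
  reported score is still the scorer's value for that sequence.
* **Seeding.** The run seed derives per-scorer and per-round child
  seeds, so any round is reproducible in isolation.

The scorer contract is deliberately minimal — any function mapping RNA
strings to `[0, 1]` — so trained classifiers (`make_scorer()`) and
rigged test doubles (`make_rigged_scorer()`) are interchangeable.

## Secondary-structure deduplication

MCTS output is highly redundant near its favourite optima. Candidates
whose predicted structures are *exactly* the same dot-bracket string
are collapsed to the best-scoring representative (ties: lexicographically
smallest sequence), and the result is sorted by score.

The default folder is a built-in Nussinov-style maximum base-pairing
dynamic program: admissible pairs AU/UA, GC/CG, GU/UG; hairpin loops
enclose at least 3 unpaired bases; traceback is deterministic (pairing
preferred over leaving the left end unpaired, leftmost admissible
partner first), so folding — and therefore deduplication — is
reproducible. An RNAfold-compatible external backend can be selected
instead; it predicts minimum-free-energy structures, which generally
differ from maximum-pairing ones. This matters less than it may seem:
structure identity is used here only as a grouping key for redundancy
removal, never as a binding-affinity claim, and the backend used is
recorded in the output's provenance. A missing external tool is a loud
error, never a silent fallback. The builtin path is implemented in
C++ (Rcpp) because deduplicating a full run folds tens of thousands of
sequences.

## The synthetic benchmark generator

`generate_api_dataset()` emulates the *shape* of published interaction
benchmarks — RNA aptamers of 20–90 nt, proteins of 50–400 residues, a
1:3 positive:negative ratio — with a fully known interaction rule:
each protein hashes (deterministically, from its first `motif_length`
residues; see `motif_for_protein()`) to an RNA motif; positives carry
the motif at a uniform position; negatives are uniform RNA
rejection-sampled to be motif-free, making the planted rule exact.
Labels are then flipped with probability `noise_rate` (default 0.1) to
emulate annotation noise, with the pre-noise truth kept alongside.

Two generator choices deserve justification:

* **A shared protein pool** (default 8 targets). Real benchmarks pair
  many aptamers with a recurring set of proteins, and composition
  encoders cannot read a protein's *sequence order* — so a classifier
  can only associate a protein's compositional fingerprint with its
  motif if that protein recurs across training pairs. Train and
  held-out sets are therefore drawn over the same pool
  (`cmd_synth()`, or `generate_api_dataset(cfg, proteins = ...)`).
* **Clean held-out labels.** Label noise belongs in training data (it
  is a property of annotation pipelines); evaluation is against the
  known ground truth, which the generator can supply exactly. With a
  1:3 ratio and 10% flips, evaluating against *noisy* labels would cap
  even a perfect classifier near MCC 0.76, conflating annotation noise
  with model quality.

**What passing tests show — and what they don't.** The generator's
uniform sequences have none of real data's composition bias, SELEX
enrichment structure, or binding thermodynamics; a high MCC here shows
the pipeline recovers a planted compositional signal, not that it
predicts real binding. There is also a hard information ceiling worth
stating plainly: the planted motif is a 4-mer, while every aptamer
encoder in the grid sees at most trinucleotide composition. A negative
sequence can contain all of the motif's constituent 3-mers without
containing the motif, and for aptamers in the 20–90 nt range this
happens so often that even an oracle that knows each protein's motif
and checks 3-mer presence tops out near MCC ≈ 0.7 — and a forest
trained on encoded features stays well below that. At short aptamer
lengths (20–30 nt) chance 3-mer co-occurrence is rare and the signal
becomes clearly recoverable, which is why the learnability and
noise-degradation property tests run there. Across noise rates
{0, 0.1, 0.2} the recovered MCC falls, but the 0 → 0.1 decrement sits
below sampling resolution at test scale (bagging absorbs mild label
noise), so the tests assert the decidable comparisons: noise 0 and
0.1 both beat noise 0.2.

## Numerical and procedural details

* Tie-breaks are fixed everywhere randomness is not intended:
  committed-base ties (visits, then label order), dedup ties
  (lexicographic sequence), selection ties (fewest trees, then order),
  Nussinov traceback (leftmost pairing). UCT ties during descent are
  broken uniformly at random by design — they are part of the search's
  exploration.
* All RNG flows from a single integer seed per entry point;
  `.Machine$integer.max`-bounded child seeds keep everything in 32-bit
  range.
* Degenerate inputs fail fast with typed conditions
  (`aptgen_too_short`, `aptgen_invalid_alphabet`,
  `aptgen_bad_config`, …) carrying positions or record indices.
* Test problem sizes are the package's choices for a fast, convincing
  suite: encoder oracles run on ~100 random sequences per family;
  folding is cross-checked exhaustively for lengths ≤ 12 (where full
  enumeration is feasible); sampler-convergence runs use N = 15,
  M = 2000 across five seeds; end-to-end learnability uses the
  generator's default 200/600 pairs with 50 selection repeats, and the
  round/default checks use a constant stub scorer so `M = 5000` runs
  in seconds.

## Known limitations

* The classifier is only as good as composition-level features allow;
  order-aware or structure-aware encoders are out of scope.
* The committed-base criterion ("highest mean score") is one defensible
  reading of an underdetermined rule; alternatives (cumulative score,
  visit count) exist and would occasionally commit differently.
* Builtin folding maximizes pairing, not free energy; its structures
  are a dedup key, not thermodynamic predictions.
* No docking, 3D modelling, or binding validation: the output is a
  ranked candidate list for downstream experimental or structural
  work.
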