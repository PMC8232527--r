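Package: aptgen
Title: Candidate RNA Aptamer Generation by Monte Carlo Tree Search with
    Random-Forest Interaction Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates candidate RNA aptamer sequences of a chosen length
    for a target protein. A random-forest aptamer-protein interaction
    classifier, trained on labelled sequence pairs encoded with
    composition, covariance, pseudo-composition and conjoint-triad
    features, is used as the score function of an iterative forward
    Monte Carlo tree search over a directional-base sequence tree.
    Generated candidates are deduplicated by predicted RNA secondary
    structure (dot-bracket notation) and ranked by interaction score.
    Includes a seeded synthetic benchmark generator with a plantable
    motif interaction rule so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
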