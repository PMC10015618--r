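Package: meflow
Title: Blockwise-SFS Inference of Effective Migration and Chromosome
    Rearrangement Barriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying barriers to gene flow between a pair of
    recently diverged species from whole-genome data. Implements the blockwise
    site frequency spectrum (bSFS): variant and callable-site filtering,
    fixed-content block cutting and mutation-type tallying, an exact
    continuous-time Markov chain likelihood kernel for divergence (DIV) and
    isolation-with-migration (IM) histories, composite-likelihood model fitting
    with parametric bootstrap, precomputed likelihood grids and windowed scans
    of the effective migration rate (me) with barrier-window classification.
    Also detects chromosome fission and fusion rearrangements from whole-genome
    alignments, polarizes them against an outgroup by parsimony over marker
    co-occurrence, and provides the permutation tests that link rearrangement
    status to reduced me. A structured-coalescent simulator generates block
    tallies, VCF/BED data and synthetic rearrangement histories so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    Rcpp,
    IRanges,
    S4Vectors,
    stats,
    utils,
    ape,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
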