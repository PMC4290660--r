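Package: decoyrank
Title: Clustering, Physico-Chemical Scoring and Evaluation of Protein Decoy Pools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting native-like models from large pools of
    protein structure decoys. Implements RMSD-radius clustering with
    representative picking, a linear physico-chemical scoring metric (pcSM)
    built from solvent-accessible surface terms, secondary-structure
    penalties and a compactness measure, a staged selection protocol that
    emits five candidate structures, and CASP-style evaluation of
    predictions against a native structure by C-alpha RMSD and TM-score.
    A synthetic-data generator produces toy folds and noise-calibrated
    decoy pools with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
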