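Package: acetree
Title: Lysine Acetylation Site Prediction with Polynomial Positional
    Encodings and Flexible Neural Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts lysine acetylation sites from protein sequence.
    Peptide windows centered on candidate lysines are encoded by polynomial
    positional-influence weighting (constant, square-root and quadratic
    profiles) of physico-chemical residue properties drawn from the AAIndex
    database, and classified by a flexible neural tree whose structure is
    searched by genetic programming and whose parameters are tuned by
    particle swarm optimization. Includes confusion-based performance
    metrics in both the standard and the Chou count formulations, ROC and
    precision-recall analysis, stratified k-fold cross-validation, a
    synthetic peptide generator with a plantable position-dependent
    physico-chemical signal, and a command-line interface covering window
    bandwidth and encoder-parameter scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
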