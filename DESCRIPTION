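Package: hpscore
Title: Nine-Feature Binary Scoring and Classification of Hypothetical Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts per-protein annotation evidence (Pfam, orthology,
    protein interactions, bidirectional best BLAST hits, subcellular
    localization, functional linkages, pseudogene, homology-modelling and
    non-coding RNA signals) into nine binary feature scores and a Total
    Reliability Score, and classifies hypothetical versus functional
    proteins with from-scratch implementations of the pocket perceptron,
    Bernoulli naive Bayes, a gain-ratio decision tree and an SMO-trained
    support vector machine. Includes stratified cross-validation and
    repeated random-split evaluation with the standard confusion-matrix
    metrics (accuracy, sensitivity, specificity, precision, F1, MCC),
    correlation-based feature selection, PCA-based feature ranking,
    exhaustive subset search, Jaccard similarity of binary profiles,
    one-way ANOVA checks, and a synthetic-data generator that emulates a
    106-positive / 194-negative binary feature matrix with induced
    feature correlations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
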