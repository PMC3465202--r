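Package: genebeam
Title: Beam-Search Selection of Minimal Gene Subsets for Tumor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper gene selection for expression-based tumor classification.
    Genes are pre-ranked by the Kruskal-Wallis rank sum test, then a beam
    search (heuristic breadth-first search) grows gene subsets one gene per
    layer, keeping the w subsets with the highest cross-validated accuracy,
    until a target accuracy or depth is reached. The resulting collection of
    minimal high-accuracy subsets drives a majority-voting ensemble classifier
    with a vote-ratio confidence level, an occurrence-frequency gene ranking
    with power-law diagnostics, and hypergeometric/binomial pathway enrichment
    p-values. Includes wrapped 5-NN and RBF-kernel SVM classifiers, stratified
    k-fold and Full-fold cross-validation statistics, ROC/confusion metrics,
    cross-platform gene alignment, and a seeded synthetic expression-data
    generator with planted informative genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
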