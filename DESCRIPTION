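Package: mirSig
Title: Correlation-Based Transcriptomic Signature Discovery and Projection
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery of co-expression gene signatures from microRNA-mimic
    transfection transcriptomes and their projection onto external cohorts.
    Implements LOWESS normalization against a median reference profile,
    hierarchical gene and sample clustering with uncentered Pearson
    similarity and average linkage, fractional tree cuts with cluster-level
    collective t-tests, gene-wise moderated t-statistics with
    empirical-Bayes variance shrinkage and Benjamini-Hochberg FDR control,
    Observed/Expected fold-enrichment of target lists against a whole-chip
    background, shared-target signature construction, and two-branch sample
    classification of external expression cohorts. A synthetic-data
    generator with planted co-expression clusters, scaled-inverse-chi-square
    gene variances and smooth per-sample intensity distortions makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
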