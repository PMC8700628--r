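Package: ibdclass
Title: Two-Stage Sparse PLS-DA Classification of Crohn's Disease versus
    Ulcerative Colitis from Mucosal RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distinguishes Crohn's disease (CD) from ulcerative colitis (UC)
    using gene-level RNA-seq counts from endoscopic biopsies. Counts are
    filtered, TMM-normalized and log2-CPM transformed, then classified in two
    stages: a partial least-squares discriminant analysis (PLS-DA) of
    normal-tissue CD versus UC identifies genes whose loadings align with the
    inter-class direction (largely a gut-segment confound); the strongest of
    these are pruned before a sparse PLS-DA of inflamed CD versus inflamed UC
    selects a compact per-component gene signature, tuned and evaluated by
    repeated stratified cross-validation. A negative-binomial simulator
    generates four-class count matrices with planted inflammation, disease and
    segment effects so the whole pipeline can be exercised and benchmarked
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    edgeR,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr,
    yaml
biocViews: Classification, Transcriptomics, RNASeq, Normalization,
    DimensionReduction
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
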