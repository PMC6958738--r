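Package: stsig
Title: Tag-Cluster Expression Signatures and Region Classification for
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Workflow for classifying spatial transcriptomics (ST) spots
    into tissue region classes (non-malignant, ductal carcinoma in situ,
    invasive ductal carcinoma) from spatially barcoded 3'-end sequencing
    reads.  Builds gene-model-independent expression features (ST tag
    clusters) by parametric density clustering of transcription
    termination sites, computes spot-by-cluster count matrices,
    normalizes them with median-of-ratios size factors, derives
    class-specific differential-expression signatures with a
    negative-binomial Wald test, and transfers the signatures to unseen
    tissue sections with a linear multi-class support vector machine
    evaluated by leave-one-dataset-out per-class F1 scores.  Includes an
    unsupervised PCA plus Ward clustering alternative and a synthetic
    data generator that emulates the statistical structure of breast
    cancer ST sections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    mclust,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
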