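Package: PatchSeqKit
Title: Quality Control, Feature Extraction and Taxonomy Mapping for
    Patch-seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scaled Patch-seq pipelines: online sweep quality
    control for current-clamp recordings (baseline stability, post-stimulus
    recovery, autobias, ramp termination, sweep and cell inclusion rules),
    offline action-potential detection and shape features with sparse PCA
    reduction of standardized feature vectors, transcriptomic quality scores
    (normalized marker sum, contamination, quality) against a dissociated-cell
    reference, top-down bootstrapped mapping onto a hierarchical cell-type
    taxonomy with consistency classification, and empirical ROC/AUC analyses
    linking experimental covariates to outcomes. Includes seeded synthetic
    generators for reference taxonomies, Patch-seq expression profiles,
    voltage sweeps and experiment metadata so every stage can be exercised
    and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
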