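Package: sleepwave
Title: Transcriptional Dynamics of Sleep Deprivation and Recovery Sleep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cortical gene expression across sleep
    deprivation and recovery sleep. Provides removal of unwanted variation
    (RUV) by factor analysis on negative-control genes or replicate samples
    with data-driven selection of the number of factors, empirical-Bayes
    moderated-t differential expression with positive-control diagnostics,
    cross-study integration (identifier harmonization, expression filtering,
    principal-component reporting), hierarchical clustering of log
    fold-change time courses into fast/slow/late responder classes,
    exponential-decay time-constant estimation for each cluster, and local
    gene-set enrichment with a jackknifed exact test and kappa-similarity
    term clustering. A synthetic-data generator reproduces the statistical
    structure of the study design so that every stage can be exercised and
    validated without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
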