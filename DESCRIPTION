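Package: metabograd
Title: Differential Abundance, Surgical Reversal and Transpulmonary
    Gradient Analysis for Plasma Metabolomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end inference pipeline for untargeted plasma
    metabolomics cohort studies of pulmonary vascular disease.
    Implements minimum-detected imputation, detection filtering, per-metabolite
    Box-Cox normalisation, z-scoring to healthy controls and cross-batch
    quantile normalisation; discovery/replication differential-metabolite
    testing with Bonferroni control, confounder-adjusted regression and
    comparator-group specificity tiers; single-marker ROC evaluation with
    DeLong confidence intervals and Youden cut-offs; paired quantification of
    metabolite reversal after pulmonary endarterectomy as percent correction
    of the perturbation from healthy-control levels; and multi-site
    (superior vena cava, pulmonary artery, radial artery) gradient analysis
    with false-discovery-rate control, Fisher's-exact pathway enrichment,
    Spearman relevance networks and clinical-severity correlations. A
    synthetic-cohort generator with a planted-truth ledger supports
    calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
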