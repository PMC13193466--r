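Package: miRtraj
Title: Pre-Diagnostic Circulating miRNA Trajectories in Matched
    Case-Control Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for nested case-control studies of
    circulating microRNAs measured on digital counting (nCounter-style)
    panels before cancer diagnosis. Provides count normalization
    (background correction, spike-in scaling, sample content scaling,
    quantile normalization), per-miRNA conditional logistic regression
    on decile-coded expression within lead-time windows with
    Benjamini-Hochberg false discovery rate control, case/control
    log-ratio trajectory modelling over the decade preceding diagnosis
    (including a random-intercept model for repeated draws), and
    time-dependent AUC evaluation of nested risk-prediction models with
    bootstrap internal validation. A synthetic matched-cohort generator
    emulating the multi-cohort study structure makes every stage
    testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    limma,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    knitr,
    rmarkdown
biocViews: Normalization, Regression, Classification, miRNA,
    Epigenetics, ImmunoOncology
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'MiRCountSet-class.R'
    'association.R'
    'io.R'
    'miRtraj-package.R'
    'normalize.R'
    'pipeline.R'
    'risk.R'
    'simulate.R'
    'trajectory.R'
    'utils.R'
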