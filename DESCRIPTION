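Package: fcreconfig
Title: Rest-to-Task Functional Network Reconfiguration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of functional connectivity (FC)
    reconfiguration between resting state and a spatial working memory task
    with three memory loads. Provides ROI-level signal conditioning
    (task-activation and nuisance regression, detrending, band-pass
    filtering, framewise-displacement motion QC), Fisher-z FC matrix
    construction per condition, global / intranetwork / internetwork FC
    similarity for rest-task, stepwise, and within-load comparisons,
    behavioral scoring, group-by-load inference with Tukey post hocs and a
    per-network Bonferroni gate, covariate-adjusted partial Spearman
    brain-behavior associations with bootstrap standard errors, and a
    synthetic two-group cohort generator with planted group, load, and
    brain-behavior structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    emmeans,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'parcellation.R'
    'io.R'
    'behavior.R'
    'cohort-spec.R'
    'utils.R'
    'conditioning.R'
    'connectivity.R'
    'stats.R'
    'reconfiguration.R'
    'simulate.R'
    'pipeline.R'
    'studies.R'
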