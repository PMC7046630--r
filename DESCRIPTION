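Package: methylmlm
Title: Mixed Linear Models for Methylome-Wide Association and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Methylome-wide association analysis of case-control traits with
    mixed linear models: omics relationship matrices (ORM) and REML estimation
    of the variance captured by genome-wide DNA methylation, per-probe
    association engines (ordinary least squares, ORM-PC-adjusted, single- and
    multi-random-component mixed models with proximal-window exclusion),
    BLUP probe effects and methylation profile scores with out-of-sample AUC
    classification, reference-based blood cell-type deconvolution, and a
    synthetic whole-blood 450K-like cohort generator with configurable
    cell-composition, batch, and sparse causal-probe structure for method
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
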