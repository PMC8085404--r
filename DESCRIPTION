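Package: panelsubtype
Title: Molecular Subtyping of Non-Small Cell Lung Cancer from Targeted
    Gene-Panel Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for molecular subtyping of non-small cell lung cancer
    (adenocarcinoma versus squamous cell carcinoma) from small-volume
    targeted expression panels such as NanoString nCounter counts or
    RNA-Seq FPKM-UQ. Implements per-sample (individual) normalization
    against housekeeping genes, a published 15-signature-gene logistic
    classifier, an elastic-net penalized logistic regression training
    engine with intensive resampling and convergence diagnostics,
    specificity-targeted dual-threshold calling with an indeterminate
    zone, ROC/c-statistic and Kolmogorov-Smirnov evaluation including
    profiling of not-otherwise-specified (NOS) cases, and a seeded
    synthetic-cohort generator for power and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
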