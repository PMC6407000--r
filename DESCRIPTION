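Package: miRsurv
Title: Prognostic Modelling of Circulating miRNA qPCR Panels with Censored
    Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of serum/plasma miRNA qPCR arrays in relation
    to right-censored survival endpoints. Covers spike-in and reference-gene
    Ct normalization with data-driven (NormFinder-style) stability ranking,
    exclusion and K-nearest-neighbour imputation of below-detection wells,
    univariate Cox screening with Benjamini-Hochberg false discovery control,
    elastic-net Cox models with unpenalized clinical covariates and a cap on
    the number of selected markers, and a Simon-type validation engine:
    leave-one-out cross-validated prognostic indices, risk-group Kaplan-Meier
    curves, IPCW time-dependent ROC curves, and permutation tests. Includes a
    synthetic cohort generator emulating the statistical structure the
    analysis assumes, so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
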