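Package: codscreen
Title: Cause-of-Death Screening from Postmortem Metabolomics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for screening forensic autopsy cases into
    cause-of-death (CoD) groups from untargeted LC-HRMS peak-intensity
    feature tables. Implements probabilistic quotient normalization,
    retention-time filtering, log/unit-variance scaling, NIPALS-based PCA,
    PLS and multi-class OPLS-DA with 7-fold cross-validation, Hotelling's
    T2 and DModX outlier diagnostics, per-covariate PLS confounder
    screening, VIP-based feature refinement, specificity-optimized
    ROC-threshold screening with per-group diagnostic metrics, and
    downstream univariate statistics, hierarchical clustering and m/z
    annotation. Ships a synthetic cohort generator emulating a five-group
    forensic study population with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
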