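Package: fcmvpa
Title: Functional-Connectivity Multivariate Pattern Analysis with Linear
    Support Vector Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state functional-connectivity (FC) biomarker analyses
    for case-control neuroimaging cohorts: Fisher-z edge features from ROI
    time series (detrending, nuisance regression, bandpass filtering),
    mass-univariate edge-wise group statistics with FDR control,
    leave-one-out cross-validated linear SVM classification with embedded
    weight-ranked feature selection and permutation inference,
    support-vector regression of clinical scores with per-fold univariate
    feature filtering, cross-site validation, Bland-Altman agreement, and
    a two-site synthetic cohort generator for end-to-end validation of the
    full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    MASS,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
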