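Package: cushval
Title: Canine Cushing's Syndrome Prediction Tool and External Validation
    Toolkit
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the published points-based prediction tool and
    logistic regression model for diagnosing spontaneous Cushing's
    syndrome (hypercortisolism) in dogs, together with the complete
    external-validation workflow for clinical prediction models:
    case-mix (transportability) comparison with exact contingency-table
    tests, logistic recalibration (calibration-in-the-large and
    calibration slope), Hosmer-Lemeshow goodness of fit, ROC curves and
    the c-statistic with DeLong confidence intervals, threshold
    diagnostics (sensitivity, specificity, predictive values),
    coefficient refitting with separation detection, urine
    corticoid-to-creatinine ratio (UCCR) and oral high-dose
    dexamethasone suppression test interpretation, ALIVE case
    adjudication, and a synthetic cohort generator with controllable
    miscalibration for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
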