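Package: riskfilter
Title: Online Updating of Logistic Prognostic Risk Models by Direct Particle Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuously updates the coefficients of a logistic clinical risk
    model as new patient records stream in, using a particle filter whose only
    state is the parameter vector itself (direct filtering for parameter
    estimation). Includes the model-building pipeline around the filter
    (variance and correlation screening, cross-validated L1 selection,
    random-forest importance screening, dummy encoding, and an initial
    cross-validated logistic fit), a dense-grid Bayes filter used as an
    independent reference for validating the particle filter, a synthetic
    cohort generator with planted structure and concept-drift injection, and
    confusion/ROC evaluation with before/after model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    glmnet,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
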