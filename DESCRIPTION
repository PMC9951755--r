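Package: munpredict
Title: Predicting Urinary Nitrogen Excretion of Dairy Cows from Milk Urea
    Nitrogen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-regression of literature treatment means to
    predict urinary nitrogen excretion (UN, g/d) of lactating dairy cows
    from milk urea nitrogen (MUN, mg/dL) and animal or diet covariates.
    Implements a weighted linear mixed-model engine with a single random
    study intercept and inverse-SEm-squared weights, mean and linear
    prediction-bias decomposition for published and newly fitted
    equations, backward elimination of fixed-effect terms with diet-type
    interactions, Lin's concordance correlation with location and scale
    decomposition, RMSEP and relative prediction error, and a synthetic
    treatment-mean generator with study-level structure for testing the
    full pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    MASS
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
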