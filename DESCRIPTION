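Package: agearch
Title: Age-Dependent Trait Architecture Under the Exposure-Accumulation
    Liability-Threshold Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying how the genetic
    and environmental architecture of complex traits and diseases changes
    with age. Implements liability-threshold disease simulators with and
    without exposure accumulation (environmental variance that accrues with
    age), Haseman-Elston variance-component estimators applied per age bin,
    denoised longitudinal phenotypic correlations, calibrated risk
    predictors with incident and prevalent case-control designs,
    observed-to-liability scale conversion of prediction accuracy, and
    linear age-trend tests with Monte-Carlo standard errors. A synthetic
    cohort generator provides desk-scale inputs with the statistical
    structure the analysis assumes, and a pipeline driver runs the full
    workflow from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
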