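Package: mgcfa
Title: Multi-Group Confirmatory Factor Analysis and Measurement Invariance
    for the CES-D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of mean-and-covariance-structure
    confirmatory factor models in one or several groups, with built-in factor
    structures for the 20-item Center for Epidemiological Studies Depression
    Scale (CES-D). Implements the four-step measurement-invariance sequence
    (configural, metric, scalar, uniqueness) with a partial-invariance
    constraint-release search, fit indices (RMSEA with noncentral confidence
    interval, CFI, NNFI, AIC), latent mean comparison with Hancock's
    standardized effect size, McDonald's omega reliability, and a two-group
    synthetic item-data generator so that every stage of the pipeline can be
    exercised without access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
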