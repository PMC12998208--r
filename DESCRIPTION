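Package: pfasmix
Title: Survey-Weighted Mixture Analysis of PFAS and Cardiometabolic Health
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for estimating joint associations between
    correlated per- and polyfluoroalkyl substance (PFAS) plasma
    concentrations and cardiometabolic outcomes in complex-survey data.
    Provides left-censored lognormal "fill-in" imputation below the limit
    of detection, metabolic syndrome classification and a continuous
    cardiometabolic risk score (CMRS) built from age- and sex-standardized
    residual Z-scores, survey-weighted generalized linear models with
    bootstrap replicate-weight variance (including modified Poisson
    prevalence-ratio regression), and quantile g-computation for the
    joint mixture effect with directional weight decomposition. A
    synthetic cohort generator with known ground-truth effects emulates
    restricted national-survey microdata so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
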