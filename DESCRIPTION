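Package: covbench
Title: District-Level Small-Area Estimation and Benchmarking of Health
    Intervention Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating levels and trends in maternal and child
    health intervention coverage across subnational districts from sparse,
    noisy, multi-source survey data.  Implements a three-stage small-area
    model (logit-space ordinary least squares on socio-demographic
    covariates, spatial-temporal locally-weighted residual smoothing, and
    per-district Gaussian process regression with a Matern covariance
    producing posterior draws and 95 percent uncertainty intervals), a
    two-step mixed-effects-spline plus Gaussian-process covariate
    completion model, preprocessing rules for administrative-boundary
    splits, pre-launch coverage floors and administrative spray data, and a
    benchmarking layer (population-weighted national series, composite
    coverage, socioeconomic composite, district gaps, changes and
    correlations).  A synthetic-data module generates geographies, true
    coverage surfaces and survey-style observations with known ground
    truth for recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
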