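Package: irivsca
Title: Characteristic-Band Selection for Soil Property Estimation from
    Vis-NIR Spectra via IRIV-SCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wavelength selection and estimation pipeline for predicting a
    soil property (e.g. arsenic content, ug/g) from visible and
    near-infrared reflectance spectra.  Implements iteratively retaining
    informative variables (IRIV), a wrapper selector that classifies
    wavelengths by the change in cross-validated partial least squares
    error across randomized balanced sub-models, followed by a
    Gaussian-filter / first-derivative / Gaussian-filter-again feature
    cascade screened by Spearman rank correlation (SCA).  Also provides
    SPXY calibration/validation partitioning, a uniform harness over seven
    regression models, and a synthetic soil-spectra generator with planted
    absorption features for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    e1071,
    xgboost,
    randomForest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
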