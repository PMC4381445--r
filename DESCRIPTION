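Package: feedstockNIR
Title: NIR/PLS Calibration of Composition and Reactivity in Cellulosic
    Biomass Feedstocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A chemometrics pipeline for multivariate calibration of
    near-infrared (NIR) spectra against biomass feedstock composition
    (glucan, xylan, lignin, ash; wt% dry basis) and dilute-acid
    pretreatment/enzymatic-hydrolysis reactivity (glucose and xylose
    release in g/g, glucan and xylan yield as fraction of theoretical).
    Implements SNV and Savitzky-Golay derivative spectral preprocessing,
    PCA-score Kennard-Stone calibration/validation splitting, NIPALS
    PLS-1/PLS-2 regression with leave-one-out cross-validation,
    normalized-prediction-error outlier screening, and reporting of
    RMSEC/RMSECV/RMSEP summary statistics, together with a synthetic
    Beer-Lambert spectra generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'spectra.R'
    'preprocess.R'
    'pls.R'
    'evaluate.R'
    'feedstockNIR-package.R'
    'io.R'
    'split.R'
    'outliers.R'
    'reactivity.R'
    'simulate.R'
    'workflow.R'
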