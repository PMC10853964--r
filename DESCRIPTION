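Package: hdxamend
Title: Correction and Simulation of Back- and Forward-Exchange Artifacts in
    HDX-MS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and correcting back- and forward-exchange
    artifacts in hydrogen-deuterium exchange mass spectrometry (HDX-MS)
    uptake data.  Provides a forward simulator of peptide-level relative
    fractional uptake (RFU) from per-residue protection factors and
    sequence-specific intrinsic amide exchange rates, the two-point control
    algebra that corrupts and reconstitutes RFU, a synthetic error-impact
    study of control errors on protection-factor optimization, a bounded
    smoothness-regularized protection-factor optimizer, a from-scratch
    multilayer perceptron that predicts per-peptide exchange controls from
    the variance of uncorrected uptake, random-coil-theory control
    prediction along the quench and chromatography timeline, and HDX-guided
    ranking of structural decoys with ROC/AUC native-fold classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
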