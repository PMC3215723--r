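Package: boldbci
Title: Real-Time fMRI and ECoG Decoding of Covert Visuospatial Attention
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a complete real-time BOLD decoding pipeline for
    covert visuospatial attention: pseudo-random block-design schedules,
    synthetic 4D BOLD phantoms with hemodynamically lagged activations and
    deactivations, rigid-body motion correction by sum-of-squared-difference
    minimization, an incremental mass-univariate general linear model with
    streaming t-maps, differential-contrast region-of-interest selection
    with cluster filtering, smoothness-priors detrending, a percent-signal-
    change control signal with fixed and adaptive (false-positive-rate
    constrained) thresholding, and performance scoring (shifted TPR/FPR,
    ROC sweeps, single-volume trial classification, Wolpaw information
    transfer rate, Dice overlap). Also provides a high-gamma band-power
    ECoG attention classifier with margin-based channel selection and
    leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
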