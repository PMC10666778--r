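Package: vpcsp
Title: Variance-Characteristic-Preserving Common Spatial Patterns for
    Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatial filtering for two-class motor-imagery EEG.
    Implements classical common spatial patterns (CSP) and a
    variance-characteristic-preserving variant (VPCSP) that folds a
    graph-Laplacian smoothness penalty on the spatially projected time
    series into the CSP generalized eigenproblem, suppressing transient
    outliers while keeping local band-power structure.  Includes delay
    embedding, a three-band filter bank with probabilistic fusion,
    Gaussian-process expected-improvement hyperparameter optimization,
    stratified 64/16/20 cross-validation, a calibrated synthetic
    ERD/ERS generator with ground truth, and readers for EDF recordings
    and a native epoch container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    MASS,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
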