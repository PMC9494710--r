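Package: emgrec
Title: Lightweight CNN+LSTM Gesture Recognition from Surface Electromyography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for surface electromyography (sEMG) gesture
    recognition targeting small embedded controllers. Provides Butterworth
    high-pass, notch and min-max conditioning of multichannel recordings,
    sliding-window time-domain features (MAV, WL, SSC, ZC, RMS), FFT magnitude
    and fused FFT+RMS tensor representations, four compact CNN/LSTM hybrid
    classifiers trained with an in-package RcppArmadillo engine, a flash-budget
    model-size estimator alongside exact trainable-parameter counting,
    intra/inter-experiment evaluation with confusion matrices, and a seeded
    synthetic 6-channel sEMG generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    yaml,
    arrow,
    withr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
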