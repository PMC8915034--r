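Package: ecgkit
Title: ECG Denoising, Heartbeat Segmentation and 1-D CNN Beat Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for electrocardiogram (ECG) signal analysis built
    around a reproducible benchmark of six denoising filters (median,
    Gaussian, moving-average, Savitzky-Golay, low-pass Butterworth and
    sym8/BayesShrink wavelet shrinkage) ranked by peak signal-to-noise
    ratio, followed by annotation-driven heartbeat segmentation, per-segment
    Z-score normalization, and binary beat classification with three custom
    one-dimensional convolutional neural networks trained by an embedded
    C++ engine. Includes readers and writers for WFDB-style records
    (text header plus format-212 packed binary signal) and CSV, a
    synthetic annotated-ECG generator with controlled additive noise for
    end-to-end testing, and a full classification metric suite (confusion
    counts, sensitivity, specificity, precision, F1, ROC and AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
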