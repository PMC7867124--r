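Package: pdmotor
Title: Wearable Inertial-Sensor Assessment of Parkinsonian Tremor and
    Bradykinesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for discriminating Parkinsonian
    tremor and bradykinesia from healthy age-matched controls using 6-axis
    wrist inertial recordings (3-axis accelerometer in G, 3-axis gyroscope
    in degrees per second, 100 Hz). Provides a parameterized synthetic
    cohort generator, Hampel outlier removal and zero-phase Butterworth
    band-pass filtering, temporal and spectral feature extraction
    (including approximate entropy, Grassberger-Procaccia correlation
    dimension and Welch band power), one-way ANOVA feature ranking, and
    KNN and batch self-organizing-map classification with a full
    confusion-matrix evaluation report.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    signal,
    e1071,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    withr,
    generics,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    class
Config/testthat/edition: 3
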