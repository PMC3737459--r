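Package: physioaffect
Title: Predicting Felt Musical Emotion from Peripheral Physiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for predicting felt musical emotion
    (valence and arousal on a 1-9 scale) from five channels of peripheral
    physiology: skin conductance level, photoplethysmography-derived heart
    rate, respiration, and zygomaticus/corrugator facial electromyography.
    Provides a synthetic study generator with planted physiological effects,
    signal feature extraction (zero-phase filtering, peak-detection rate
    conversion, per-participant standardization, baseline subtraction),
    Pearson correlation and stepwise forward regression, a 5-5-2
    backpropagation network trained by full-batch gradient descent, a
    sign-preserving connection-weight contribution analysis, and
    error/accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
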