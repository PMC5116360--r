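Package: hrvmp
Title: Matching-Pursuit Features and GA/KNN Screening for Short-Term Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens short-term (256-beat) RR-interval segments for congestive
    heart failure. Raw beat-to-beat intervals are resampled to an evenly
    spaced 1024-sample heart-rate-variability segment, detrended with a
    smoothness-priors filter, and decomposed by greedy matching pursuit over
    an overcomplete Gabor dictionary. Sixteen features summarising residual
    energy decay, Welch band powers, decomposition entropy and atom
    centre-frequency distribution feed a k-nearest-neighbour classifier whose
    feature subset is chosen by a genetic algorithm under 23-fold
    cross-validation. Includes a calibrated synthetic RR-series generator for
    normal-sinus-rhythm-like and heart-failure-like cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
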