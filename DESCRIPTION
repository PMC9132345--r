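Package: spiketypes
Title: Unit-Type Classification and Temporal-Coding Analysis of Cortical Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying extracellular single units into regular-spiking,
    fast-spiking and bursting classes from spike-timing and waveform features
    (interspike-interval and log-ISI histograms, autocorrelogram contrast, burst
    statistics, trough-to-peak width and spectral width), both by consensus criteria
    and by PCA plus Gaussian-mixture clustering; temporal-coding metrics (adaptation
    index, vector strength with Rayleigh significance, shuffled-autocorrelogram
    correlation index); single-unit stimulus decoding with the Victor-Purpura spike
    metric and transmitted information; and pseudopopulation time-binned decoding.
    Includes a seeded synthetic-session generator that emulates the statistical
    structure of the unit classes so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
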