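Package: rfdtools
Title: Isometric Dynamometry Traces, Rate of Force Development, and
    Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing maximal isometric force-time traces from
    hand-held and fixed dynamometers. Preprocesses raw traces with zero-phase
    low-pass Butterworth filtering and cubic-spline resampling to a uniform
    grid, computes muscle strength (peak force) and the family of
    rate-of-force-development (RFD) algorithms used in clinimetric studies
    (time to peak force, percent-of-peak-force windows, moving-window peak
    slopes), and runs the standard reliability and validity battery:
    ICC(2,1) with F-based confidence intervals, standard error of
    measurement, minimal detectable change, Pearson and Lin concordance
    correlations, and standard or regression-based Bland-Altman limits of
    agreement. Includes a synthetic-data generator with closed-form ground
    truth for traces and multi-factor measurement cohorts.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
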