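Package: swaycomplexity
Title: Postural Complexity Analysis of Trunk-Worn IMU Acceleration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the magnitude and temporal structure of
    postural sway from trunk-worn accelerometer recordings of quiet standing.
    Provides the full analysis chain: reading delimited IMU exports,
    tilt-correction to the anatomical frame, anti-aliased downsampling,
    zero-phase band-pass filtering and a windowed standard-deviation artifact
    screen; four sway measures (root mean square, sample entropy, the
    Rosenstein largest Lyapunov exponent with average-mutual-information and
    false-nearest-neighbour embedding selection, and a frequency-banded
    detrended fluctuation analysis scaling exponent); a reliability and
    inference layer (three-way mixed ANOVA with Cohen's f, Benjamini-Hochberg
    post-hoc comparisons, one-way random intraclass correlation with a
    reliability gate, and bias-corrected accelerated bootstrap intervals); and
    a seeded synthetic sway-cohort generator for validation and power studies.
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
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
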