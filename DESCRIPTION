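Package: ssvepdyn
Title: Time-Resolved Suppression Analysis for Steady-State Visual Evoked
    Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for frequency-tagged steady-state visual
    evoked potential (SSVEP) experiments that measure how divisive
    suppression between two flickering stimuli evolves over the first
    seconds of stimulation. Provides a synthetic-data generator based on a
    dynamic normalization forward model with exponentially reweighted
    suppressive gain, epoched-recording input/output, exact-frequency
    sliding-window Fourier amplitude time courses, outlier rejection of
    trials by the Mahalanobis distance of complex Fourier coefficients,
    suppression-ratio time courses in decibels with windowed effect sizes
    and intermodulation indices, and nonparametric cluster-corrected
    permutation tests for increasing suppression and for group
    differences.
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
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
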