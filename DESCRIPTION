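Package: sleepspectra
Title: Sleep-EEG Spectral Correlates of Cognitive Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for mass-univariate analysis of
    full-night sleep EEG power spectra against psychometric trait scores.
    Reads polysomnography (EDF), hypnograms and artifact masks; estimates
    amplifier frequency-response calibration curves from sinusoid sweeps and
    corrects power spectral densities for device gain; computes calibrated
    relative log-power spectra per sleep state (NREM, REM) with Hann-tapered
    overlapping windows; converts Raven APM and Culture Fair Test raw scores
    to a composite Raven Equivalent Score via pluggable norm tables; maps
    age-partial Pearson correlations over the electrode-by-frequency grid per
    sex; controls family-wise error with the Rueger-area decision procedure
    and a seeded max-statistic permutation test with missing-channel
    imputation; and compares correlations between sexes with Fisher's r-to-z
    test. Ships a synthetic-cohort generator with planted effects so every
    stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
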