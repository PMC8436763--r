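Package: flimca
Title: Fluorescence-Lifetime (FLIM) Quantification of Presynaptic Calcium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for time-correlated
    single-photon-counting (TCSPC) fluorescence lifetime measurements of
    presynaptic calcium with a single-wavelength indicator (OGB-1).
    Generates synthetic calibration decay histograms and tornado-scan photon
    count cubes, decodes nanomolar free-calcium concentrations with the
    Normalized Total Count (NTC) statistic and a fitted logistic calibration,
    estimates resting calcium and saturation-corrected spike-evoked calcium
    entry from combined lifetime and intensity readouts, and runs the
    branch-order and paired-condition statistics used for nested bouton
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
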