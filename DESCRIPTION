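Package: mshdx
Title: Millisecond Hydrogen/Deuterium-Exchange Kinetics and Quench-Flow Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for millisecond-resolved hydrogen/deuterium-
    exchange mass spectrometry (HDX-MS). Computes sequence-dependent intrinsic
    amide exchange rates from published reference tables, corrects observed
    deuterium uptake for back-exchange using maximally deuterated references,
    fits multi-phase stretched-exponential uptake kinetics with F-test model
    selection, and derives segment-averaged protection factors. Also provides
    the quench-flow instrument design math: loop-volume calibration by dye
    dilution, Reynolds-number turbulence constraints, millisecond time-point
    planning across continuous-flow and stop-flow modes, and chemical-clock
    (DNPA hydrolysis) timing validation. A synthetic-data generator produces
    uptake tables with known ground truth so every stage is testable without
    instrument data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
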