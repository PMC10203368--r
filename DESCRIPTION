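Package: hydrodr
Title: Time-Lapse Dielectric Relaxation Analysis of Protein Hydration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-lapse microwave dielectric relaxation
    (DR), terahertz time-domain (THz-TDS), and NMR methyl-intensity data from
    aqueous protein solutions. Implements multi-Debye complex-permittivity
    models, Open/Short/Standard coaxial-probe calibration via the bilinear
    (Moebius) reflection map, real-axis-constrained Nyquist semicircle fitting
    with extrapolated relaxation limits, the delta-r standing-wave deviation
    statistic and its baseline-subtracted peak, difference-spectrum band
    statistics with error propagation, sequence-based methyl enumeration with
    intensity normalisation and pathway correlation, and a one-dimensional
    slab reflection model of the sample cell with field dosimetry. A seeded
    synthetic-data generator emulates the full time-lapse experiment so that
    every stage of the pipeline can be verified end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
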