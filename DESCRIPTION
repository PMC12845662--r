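Package: embryoppg
Title: Photoplethysmography-Based Chicken Embryo Viability Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for optical (photoplethysmography,
    PPG) detection of chicken embryo viability. Provides a seeded synthetic
    generator of carrier-modulated embryonic PPG traces, digital lock-in
    (phase-sensitive) demodulation to recover the pulse envelope, baseline-drift
    suppression by correlation with a zero-mean triangular kernel, linear-phase
    FIR low-pass filtering, Short-Time Fourier Transform time-frequency
    analysis, and a rule-based viable/non-viable classifier built on amplitude,
    dominant-frequency, spectral-concentration and periodicity features, with
    batch screening and multi-day monitoring workflows.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
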