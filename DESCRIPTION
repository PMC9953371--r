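Package: radarvitals
Title: Non-Contact Vital Signs from Continuous-Wave Doppler Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and signal-processing toolkit for continuous-wave
    (CW) Doppler radar monitoring of respiration rate (RR) and heart rate
    (HR) without body contact. Generates phase-modulated quadrature (I/Q)
    baseband records from a chest-displacement model with oscillator phase
    noise, DC offsets and channel imbalance; recovers chest motion by
    four-quadrant arctangent demodulation with phase unwrapping and
    streaming DC removal; estimates RR and HR in beats/breaths per minute
    by band-limited spectral peak finding with sub-bin interpolation, in
    batch and per-refresh-tick streaming modes; scores I/Q waveform quality
    (posture and signal-strength effects); and evaluates accuracy on
    synthetic patient cohorts with median/STDEV error statistics grouped by
    covariates. Includes a command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
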