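Package: vocalradar
Title: Vocal-Fold Vibration Tracking from Continuous-Wave Radar Baseband
    Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-acoustic recovery of the time-varying speech fundamental
    frequency from 24-GHz continuous-wave Doppler radar quadrature baseband
    recordings. Simulates millimetre-scale glottal displacement and the I/Q
    baseband it induces, demodulates the phase by complex signal
    demodulation, isolates the vibration-bearing component with a
    from-scratch Variational Mode Decomposition (ADMM in the frequency
    domain), selects the mode closest to a cepstrum fundamental-frequency
    reference, and tracks the instantaneous frequency via the Hilbert
    transform with rectangular-window smoothing. Includes cepstrum and
    extremum-spacing acoustic references, per-utterance relative-error
    scoring, WAV/CSV interfaces and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
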