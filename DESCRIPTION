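Package: hearsim
Title: Binaural Beamforming, Time-Frequency Enhancement and Simulated
    Speech-Reception-Threshold Experiments for Hearing Aids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing chain for a simulated pair of behind-the-ear
    hearing aids with four microphones (front and back on each ear).  Provides
    an STFT analysis/synthesis engine, a synthetic-scene generator (rigid-sphere
    head model, speech-shaped and babble noise, reverberant tails, adaptive
    gain control and trial assembly), binaural and bilateral MVDR beamformer
    design from calibration recordings, three time-frequency enhancement
    regimes (mask-informed log-MMSE with a trainable mask estimator, Wiener
    gains with speech-presence-probability noise tracking, and per-band Kalman
    amplitude filtering), NAL-R hearing-loss compensation, and an adaptive
    staircase speech-reception-threshold experiment runner with parametric
    simulated listeners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    pracma,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
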