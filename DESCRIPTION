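Package: sfgmodel
Title: Stochastic Figure-Ground Stimuli and the Temporal Coherence Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesis of stochastic figure-ground (SFG) tone-cloud stimuli
    (random multi-tone chords with an embedded coherent "figure") for six
    psychophysical experiment designs, together with a two-stage temporal
    coherence model of auditory figure-ground segregation: a log-frequency
    auditory spectrogram front end, constant-Q modulation-rate filtering of
    the channel envelopes, and windowed cross-channel coherence matrices
    whose off-diagonal maximum indexes figure salience. Includes
    signal-detection (d-prime) utilities for yes/no and AXB response tables
    and configuration-driven reproduction of the experimental grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
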