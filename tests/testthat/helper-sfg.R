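# shared fixtures for the test suite (all built in code)

exp1_config <- function(coherence = 6, duration = 7, ...) {
  sfg_config(chord_duration_ms = 50, n_chords = 40, coherence = coherence,
             figure_duration_chords = duration, ...)
}

# a small synthetic rate response for coherence-stage unit tests
toy_rate_response <- function(values, rate_hz = 10, frame_rate_hz = 400) {
  structure(list(values = values, rate_hz = rate_hz,
                 frame_rate_hz = frame_rate_hz),
            class = "sfg_rate_response")
}

# independent normal-quantile oracle (inverse error function route)
z_oracle <- function(p) sqrt(2) * pracma::erfinv(2 * p - 1)
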