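# Auditory spectrogram front end: a constant-Q bank of Gaussian band-pass
# filters on a log-frequency axis, with the channel envelope extracted as the
# magnitude of the band-limited analytic signal. The filtering, Hilbert
# envelope, envelope low-pass and resampling to the frame rate are realized
# in one exact step in the frequency domain: the FFT coefficients inside a
# channel's passband are demodulated to baseband and inverse-transformed at
# the frame rate, which band-limits the envelope to frame_rate/2 (further
# capped by envelope_cutoff_hz) by construction.

#' Front-end configuration
#'
#' @param channels_per_octave Log-frequency channel density (default 24,
#'   matching the 1/24-octave stimulus pool so that every pool frequency has
#'   a dedicated channel).
#' @param f_lo,f_hi Channel center-frequency range in Hz (default 125--8000).
#' @param envelope_cutoff_hz Envelope low-pass cutoff (default 150 Hz).
#' @param frame_rate_hz Envelope sampling rate (default 400 Hz, ten times
#'   the highest modulation rate used by the coherence model).
#' @param filter_q Quality factor of the band-pass bank: center frequency
#'   over FWHM bandwidth. The default (\code{NULL}) sets the bandwidth so
#'   adjacent channels cross near -3 dB, i.e. one channel spacing -- a
#'   sharpened tonotopic representation in which a pure tone appears as a
#'   narrow line, as cortical models assume after lateral inhibition.
#'   Smaller values give broader, more cochlea-like filters.
#' @param compression If \code{TRUE}, apply a cube-root compressive
#'   nonlinearity to the envelopes (off by default; the coherence statistic
#'   is normalized, which makes compression largely neutral).
#' @return An object of class \code{sfg_frontend_config}.
#' @export
frontend_config <- function(channels_per_octave = 24, f_lo = 125, f_hi = 8000,
                            envelope_cutoff_hz = 150, frame_rate_hz = 400,
                            filter_q = NULL, compression = FALSE) {
  if (is.null(filter_q)) {
    # FWHM of one channel spacing: adjacent filters cross at -3 dB
    filter_q <- 1 / (2^(1 / (2 * channels_per_octave)) -
                     2^(-1 / (2 * channels_per_octave)))
  }
  stopifnot(f_lo > 0, f_hi > f_lo, channels_per_octave > 0,
            frame_rate_hz > 0, envelope_cutoff_hz > 0, filter_q > 0)
  structure(
    list(channels_per_octave = channels_per_octave, f_lo = f_lo, f_hi = f_hi,
         envelope_cutoff_hz = envelope_cutoff_hz,
         frame_rate_hz = frame_rate_hz, filter_q = filter_q,
         compression = compression),
    class = "sfg_frontend_config"
  )
}

frontend_channel_freqs <- function(cfg) {
  n_ch <- round(cfg$channels_per_octave * log2(cfg$f_hi / cfg$f_lo))
  cfg$f_lo * 2^((0:(n_ch - 1)) / cfg$channels_per_octave)
}

#' Compute the auditory spectrogram of a waveform
#'
#' Band-pass filters the waveform into log-spaced channels (Gaussian
#' magnitude response, adjacent channels crossing at -3 dB) and returns the
#' low-passed Hilbert envelope of every channel, sampled at the frame rate.
#'
#' @param w An \code{sfg_waveform} (or a numeric vector plus \code{fs}).
#' @param cfg A \code{\link{frontend_config}}.
#' @param fs Sample rate, required when \code{w} is a bare numeric vector.
#' @return An object of class \code{sfg_spectrogram}: \code{env} (channels x
#'   frames, non-negative), \code{channel_freqs} (Hz) and
#'   \code{frame_rate_hz}.
#' @export
compute_spectrogram <- function(w, cfg = frontend_config(), fs = NULL) {
  if (inherits(w, "sfg_waveform")) {
    x <- w$samples
    fs <- w$sample_rate_hz
  } else {
    x <- as.numeric(w)
    if (is.null(fs)) stop("fs is required for a bare numeric waveform")
  }
  if (length(x) == 0) stop("waveform is empty")
  if (fs < 2 * cfg$f_hi)
    stop("invalid parameters: sample rate below 2 * f_hi")
  n <- length(x)
  n_frames <- max(4L, as.integer(round(n * cfg$frame_rate_hz / fs)))
  fc <- frontend_channel_freqs(cfg)
  X <- stats::fft(x)
  bin_hz <- fs / n
  half <- n_frames %/% 2
  offs <- (-half):(n_frames - half - 1)
  env <- matrix(0, nrow = length(fc), ncol = n_frames)
  eff_rate <- n_frames * bin_hz  # actual envelope sampling rate of the slice
  lp <- abs(offs * bin_hz) <= min(cfg$envelope_cutoff_hz, eff_rate / 2)
  for (k in seq_along(fc)) {
    # Gaussian magnitude response, FWHM = fc / Q
    sigma <- fc[k] / (cfg$filter_q * 2 * sqrt(2 * log(2)))
    c0 <- round(fc[k] / bin_hz)
    bins <- c0 + offs
    gain <- exp(-((bins * bin_hz - fc[k])^2) / (2 * sigma^2))
    gain[bins <= 0 | bins >= n / 2] <- 0
    sel <- lp & gain > 1e-8
    slice_c <- complex(length.out = n_frames)
    slice_c[sel] <- 2 * X[(bins[sel] %% n) + 1] * gain[sel]
    # reorder so that negative offsets wrap to the top of the slice spectrum
    spec <- complex(length.out = n_frames)
    spec[(offs %% n_frames) + 1] <- slice_c
    env[k, ] <- Mod(stats::fft(spec, inverse = TRUE)) / n
  }
  if (cfg$compression) env <- env^(1 / 3)
  new_spectrogram(env, fc, eff_rate)
}

new_spectrogram <- function(env, channel_freqs, frame_rate_hz) {
  structure(list(env = env, channel_freqs = channel_freqs,
                 frame_rate_hz = frame_rate_hz),
            class = "sfg_spectrogram")
}

#' @export
print.sfg_spectrogram <- function(x, ...) {
  cat(sprintf("<sfg_spectrogram> %d channels x %d frames at %.1f Hz\n",
              nrow(x$env), ncol(x$env), x$frame_rate_hz))
  invisible(x)
}

#' Persist a spectrogram as CSV (frames x channels)
#'
#' The header row carries the channel center frequencies in Hz.
#'
#' @param s An \code{sfg_spectrogram}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_spectrogram_csv <- function(s, path) {
  m <- t(s$env)
  colnames(m) <- sprintf("%.2f", s$channel_freqs)
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}
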