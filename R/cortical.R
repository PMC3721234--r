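# Cortical stage: constant-Q modulation-rate filtering of every spectrogram
# channel (a wavelet-style decomposition of the channel envelopes) and an
# optional spectral-scale (ripple-density) filter along the tonotopic axis.

#' Constant-Q modulation-rate filter
#'
#' Convolves every channel envelope with a complex Gabor kernel centered at
#' \code{rate_hz}. The kernel is a Gaussian-windowed complex exponential,
#' truncated to \code{cycles} cycles of the rate, made exactly zero-mean (so
#' a constant envelope yields zero output) and normalized to unit gain at
#' the center rate. With \code{q = 1} the amplitude response has a full width
#' at half maximum equal to the center rate, so the bank is constant-Q.
#'
#' @param s An \code{sfg_spectrogram}.
#' @param rate_hz Center modulation rate in Hz.
#' @param q Quality factor (center rate / FWHM bandwidth), default 1.
#' @param cycles Kernel length in cycles of the center rate, default 4.
#' @return An object of class \code{sfg_rate_response}: \code{values}
#'   (complex channels x frames), \code{rate_hz}, \code{frame_rate_hz}.
#' @export
rate_filter <- function(s, rate_hz, q = 1, cycles = 4) {
  stopifnot(inherits(s, "sfg_spectrogram"), rate_hz > 0, q > 0, cycles > 0)
  fr <- s$frame_rate_hz
  if (fr < 4 * rate_hz)
    stop("invalid parameters: rate too high for the frame rate (need >= 4x)")
  h <- gabor_rate_kernel(rate_hz, fr, q, cycles)
  values <- convolve_rows_same(s$env, h)
  structure(list(values = values, rate_hz = rate_hz, frame_rate_hz = fr),
            class = "sfg_rate_response")
}

gabor_rate_kernel <- function(rate_hz, frame_rate_hz, q = 1, cycles = 4) {
  half <- max(1L, ceiling(cycles / rate_hz * frame_rate_hz / 2))
  t <- ((-half):half) / frame_rate_hz
  sigma_f <- rate_hz / (q * 2 * sqrt(2 * log(2)))  # FWHM = rate / q
  sigma_t <- 1 / (2 * pi * sigma_f)
  h <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * rate_hz * t)
  h <- h - mean(h)                                  # exact DC rejection
  h / sum(h * exp(-2i * pi * rate_hz * t))          # unit gain at center rate
}

# FFT-based "same" convolution of every row of m with kernel h (odd length).
# Rows are zero-padded: a stimulus is silent outside its own extent, so the
# filter sees genuine onsets/offsets at the signal edges (any causal
# band-pass does the same).
convolve_rows_same <- function(m, h) {
  n <- ncol(m)
  l <- length(h)
  pad <- n + l - 1
  H <- stats::fft(c(h, complex(length.out = pad - l)))
  M <- stats::mvfft(rbind(t(m), matrix(0, pad - n, nrow(m))))
  out <- stats::mvfft(M * H, inverse = TRUE) / pad
  off <- (l - 1) / 2
  t(out[(off + 1):(off + n), , drop = FALSE])
}

#' Spectral-scale (ripple-density) filtering of a spectrogram
#'
#' Filters every time frame along the log-frequency axis with a band-pass
#' kernel tuned to the given ripple density, implemented as a one-sided
#' Gaussian in the channel-FFT domain (an analytic signal along frequency)
#' with the spectral DC removed; the magnitude is returned, so the result is
#' again a non-negative spectrogram. A flat spectral profile maps to zero.
#'
#' @param s An \code{sfg_spectrogram} with log-spaced channels.
#' @param scale_cyc_per_oct Ripple density the filter is tuned to, in cycles
#'   per octave (8 by default in the model; 4 for the steeper ramped-figure
#'   variant).
#' @param q Quality factor on the scale axis (FWHM = scale / q), default 1.
#' @param output \code{"magnitude"} (default) returns the non-negative
#'   ripple envelope; \code{"real"} returns the signed ripple contrast,
#'   which preserves the ripple phase. The phase matters for moving
#'   figures: a frequency trajectory sweeping at velocity v octaves/s
#'   through a ripple filter of density s cycles/octave imposes a coherent
#'   temporal oscillation at s*v Hz on every channel along its path, and
#'   only the signed output carries it into the rate-filtering stage.
#' @return An \code{sfg_spectrogram} of the same shape (possibly signed for
#'   \code{output = "real"}).
#' @export
apply_spectral_scale <- function(s, scale_cyc_per_oct, q = 1,
                                 output = c("magnitude", "real")) {
  output <- match.arg(output)
  stopifnot(inherits(s, "sfg_spectrogram"), scale_cyc_per_oct > 0)
  k <- nrow(s$env)
  if (k < 4) stop("need at least 4 channels for scale filtering")
  cpo <- 1 / log2(s$channel_freqs[2] / s$channel_freqs[1])
  if (scale_cyc_per_oct > cpo / 2)
    stop("invalid parameters: scale exceeds the channel Nyquist density")
  kappa <- (0:(k - 1)) * cpo / k            # cycles/octave along the FFT axis
  sigma <- scale_cyc_per_oct / (q * 2 * sqrt(2 * log(2)))
  gain <- exp(-((kappa - scale_cyc_per_oct)^2) / (2 * sigma^2))
  gain[kappa > cpo / 2] <- 0                # one-sided (analytic) response
  gain[1] <- 0                              # remove spectral DC
  spec <- stats::mvfft(s$env)
  z <- stats::mvfft(spec * (2 * gain), inverse = TRUE) / k
  out <- if (output == "magnitude") Mod(z) else Re(z)
  new_spectrogram(out, s$channel_freqs, s$frame_rate_hz)
}

#' Transfer function of a rate kernel (for inspection)
#'
#' @param rate_hz,frame_rate_hz,q,cycles Kernel parameters as in
#'   \code{\link{rate_filter}}.
#' @param n_points Number of frequency points.
#' @return Data frame with \code{freq_hz} and \code{gain} (magnitude).
#' @export
rate_kernel_transfer <- function(rate_hz, frame_rate_hz, q = 1, cycles = 4,
                                 n_points = 512) {
  h <- gabor_rate_kernel(rate_hz, frame_rate_hz, q, cycles)
  t <- (seq_along(h) - (length(h) + 1) / 2) / frame_rate_hz
  freq <- seq(0, frame_rate_hz / 2, length.out = n_points)
  gain <- vapply(freq, function(f) Mod(sum(h * exp(-2i * pi * f * t))), 0)
  data.frame(freq_hz = freq, gain = gain)
}
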