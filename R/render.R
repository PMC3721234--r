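# Waveform rendering: each chord is a sum of equal-amplitude pure tones with
# raised-cosine edges; chords abut with 0 ms gap; noise-interleaved variants
# insert a calibrated broadband burst after every chord. Segment boundaries
# are placed by cumulative rounding so the total length in samples is exact
# even when a single segment is not an integer number of samples (25 ms at
# 44.1 kHz).

raised_cosine_edges <- function(n, ramp_samples) {
  env <- rep(1, n)
  r <- min(ramp_samples, floor(n / 2))
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * (seq_len(r) - 0.5) / r))
    env[seq_len(r)] <- up
    env[n + 1 - seq_len(r)] <- up
  }
  env
}

rms <- function(x) sqrt(mean(x^2))

segment_schedule <- function(n_chords, chord_duration_ms, noise_gap_ms,
                             sample_rate_hz) {
  kinds <- if (noise_gap_ms > 0) rep(c("chord", "noise"), n_chords)
           else rep("chord", n_chords)
  durs <- ifelse(kinds == "chord", chord_duration_ms, noise_gap_ms)
  ends <- round(cumsum(durs) * sample_rate_hz / 1000)
  starts <- c(0, ends[-length(ends)]) + 1
  data.frame(kind = kinds, chord = rep(seq_len(n_chords),
                                       each = if (noise_gap_ms > 0) 2 else 1),
             start = starts, end = ends)
}

#' Render a chordgram to a waveform
#'
#' Each chord is the sum of equal-amplitude pure tones at its component pool
#' frequencies, shaped by a raised-cosine onset/offset ramp; chords are
#' concatenated with no gap. If \code{config$noise_gap_ms > 0}, a broadband
#' white-noise burst follows every chord, scaled so that its RMS sits
#' \code{config$noise_level_db} dB above the RMS of the chord segments
#' (5 ms raised-cosine edges avoid clicks). The final waveform is
#' peak-normalized.
#'
#' @param cg An \code{sfg_chordgram}; a chordgram with no components renders
#'   to silence of the correct length.
#' @param config The \code{\link{sfg_config}} providing sample rate, ramps
#'   and noise parameters.
#' @param seed Optional seed for the noise draw (chord tones are
#'   deterministic given the chordgram).
#' @return An object of class \code{sfg_waveform}: \code{samples} (peak
#'   |amplitude| <= 1), \code{sample_rate_hz}, and a \code{segments} frame
#'   giving the sample span of every chord / noise segment.
#' @export
render_waveform <- function(cg, config, seed = NULL) {
  stopifnot(inherits(cg, "sfg_chordgram"))
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate_hz
  sched <- segment_schedule(n_chords(cg), cg$chord_duration_ms,
                            config$noise_gap_ms, fs)
  total <- sched$end[nrow(sched)]
  x <- numeric(total)
  ramp <- round(config$ramp_ms * fs / 1000)
  freqs <- cg$pool$frequencies
  chord_rows <- which(sched$kind == "chord")
  for (i in chord_rows) {
    comp <- chord_components(cg$chords[[sched$chord[i]]])
    if (length(comp) == 0) next
    n <- sched$end[i] - sched$start[i] + 1
    t <- (seq_len(n) - 1) / fs
    tone <- rowSums(sin(outer(t, 2 * pi * freqs[comp])))
    x[sched$start[i]:sched$end[i]] <- tone * raised_cosine_edges(n, ramp)
  }
  if (config$noise_gap_ms > 0) {
    chord_idx <- sequence_from_schedule(sched, "chord")
    chord_rms <- rms(x[chord_idx])
    target <- chord_rms * 10^(config$noise_level_db / 20)
    for (i in which(sched$kind == "noise")) {
      n <- sched$end[i] - sched$start[i] + 1
      if (n == 0) next
      burst <- stats::rnorm(n) * raised_cosine_edges(n, round(0.005 * fs))
      if (target > 0 && rms(burst) > 0) burst <- burst * (target / rms(burst))
      x[sched$start[i]:sched$end[i]] <- burst
    }
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  structure(list(samples = x, sample_rate_hz = fs, segments = sched),
            class = "sfg_waveform")
}

sequence_from_schedule <- function(sched, kind) {
  rows <- which(sched$kind == kind)
  unlist(lapply(rows, function(i) seq.int(sched$start[i], sched$end[i])))
}

#' RMS level difference between noise and chord segments
#'
#' @param w An \code{sfg_waveform} rendered from a noise-interleaved config.
#' @return The level of the noise segments relative to the chord segments in
#'   dB (20 log10 of the RMS ratio).
#' @export
noise_chord_level_db <- function(w) {
  stopifnot(inherits(w, "sfg_waveform"))
  noise <- sequence_from_schedule(w$segments, "noise")
  if (length(noise) == 0) stop("waveform has no noise segments")
  chords <- sequence_from_schedule(w$segments, "chord")
  20 * log10(rms(w$samples[noise]) / rms(w$samples[chords]))
}

#' @export
print.sfg_waveform <- function(x, ...) {
  cat(sprintf("<sfg_waveform> %d samples (%.1f ms) at %g Hz\n",
              length(x$samples),
              1000 * length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz))
  invisible(x)
}

#' Write a waveform as 16-bit PCM WAV
#'
#' Minimal single-channel RIFF/WAVE writer (44-byte canonical header,
#' little-endian 16-bit samples).
#'
#' @param w An \code{sfg_waveform}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "sfg_waveform"))
  pcm <- as.integer(round(pmax(-1, pmin(1, w$samples)) * 32767))
  fs <- as.integer(w$sample_rate_hz)
  n_bytes <- 2L * length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(2L * fs, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file written by \code{\link{write_wav}}
#'
#' @param path WAV file path.
#' @return An \code{sfg_waveform} (samples scaled to [-1, 1]).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1) stop("only mono PCM is supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2, size = 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  structure(list(samples = pcm / 32767,
                 sample_rate_hz = fs,
                 segments = NULL),
            class = "sfg_waveform")
}
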