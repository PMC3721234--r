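#' Stimulus configuration for SFG synthesis
#'
#' Bundles every parameter of a stochastic figure-ground stimulus: chord
#' timing, background density, figure coherence/duration, onset jitter,
#' ramped-figure step, isolated-figure and noise-interleaving variants.
#'
#' @param chord_duration_ms Duration of each chord in ms (25 or 50 in the
#'   experiment designs; any positive value is accepted).
#' @param n_chords Number of consecutive chords (40 gives 2000 ms at 50 ms).
#' @param components_min,components_max Inclusive bounds of the per-chord
#'   background component count; counts are drawn uniformly on the integers
#'   in this range (mean 10 for 5--15).
#' @param coherence Number of repeated "figure" components (0 = no figure).
#' @param figure_duration_chords Number of consecutive chords carrying the
#'   figure (0 when \code{coherence} is 0).
#' @param onset_jitter_chords Inclusive integer range of chords preceding the
#'   figure onset; default \code{c(15, 20)} places the onset 750--1000 ms
#'   post stimulus onset at 50 ms chords.
#' @param ramp_ms Raised-cosine edge applied to each chord, ms.
#' @param ramp_step Pool steps added to every figure component on each
#'   successive chord (0 = static figure; 2 and 5 give the ramped variants).
#' @param isolated If \code{TRUE} the stimulus consists of the figure chords
#'   only (background-only chords before and after the figure are dropped).
#' @param noise_gap_ms Duration of a broadband white-noise burst inserted
#'   after every chord (0 = contiguous chords).
#' @param noise_level_db Level of the noise bursts relative to the RMS of the
#'   chord segments, dB (default +12).
#' @param sample_rate_hz Rendering sample rate (default 44100).
#' @param seed Optional integer seed recorded with the stimulus; when set,
#'   \code{\link{sample_sfg_trial}} seeds its random stream from it.
#' @param pool Frequency pool (\code{\link{build_frequency_pool}}).
#' @return An object of class \code{sfg_config} (a validated list).
#' @export
sfg_config <- function(chord_duration_ms = 50, n_chords = 40,
                       components_min = 5, components_max = 15,
                       coherence = 0, figure_duration_chords = 0,
                       onset_jitter_chords = c(15, 20),
                       ramp_ms = 10, ramp_step = 0,
                       isolated = FALSE,
                       noise_gap_ms = 0, noise_level_db = 12,
                       sample_rate_hz = 44100, seed = NULL,
                       pool = build_frequency_pool()) {
  cfg <- structure(
    list(
      chord_duration_ms = chord_duration_ms, n_chords = as.integer(n_chords),
      components_min = as.integer(components_min),
      components_max = as.integer(components_max),
      coherence = as.integer(coherence),
      figure_duration_chords = as.integer(figure_duration_chords),
      onset_jitter_chords = as.integer(onset_jitter_chords),
      ramp_ms = ramp_ms, ramp_step = as.integer(ramp_step),
      isolated = isolated,
      noise_gap_ms = noise_gap_ms, noise_level_db = noise_level_db,
      sample_rate_hz = sample_rate_hz, seed = seed, pool = pool
    ),
    class = "sfg_config"
  )
  validate_sfg_config(cfg)
  cfg
}

validate_sfg_config <- function(cfg) {
  stopifnot(inherits(cfg, "sfg_config"))
  n_pool <- length(cfg$pool$frequencies)
  if (cfg$chord_duration_ms <= 0 || cfg$n_chords < 1 || cfg$sample_rate_hz <= 0)
    stop("invalid config: durations and counts must be positive")
  if (cfg$components_min > cfg$components_max || cfg$components_min < 0)
    stop("invalid config: components_min must be in [0, components_max]")
  if (cfg$components_max > n_pool)
    stop("invalid config: components_max exceeds the pool size")
  if (cfg$coherence < 0 || cfg$coherence > n_pool)
    stop("invalid config: coherence must be in [0, pool size]")
  if (cfg$coherence > 0 && cfg$figure_duration_chords < 1)
    stop("invalid config: a figure needs figure_duration_chords >= 1")
  if (length(cfg$onset_jitter_chords) != 2 ||
      cfg$onset_jitter_chords[1] > cfg$onset_jitter_chords[2] ||
      cfg$onset_jitter_chords[1] < 0)
    stop("invalid config: onset_jitter_chords must be an increasing pair >= 0")
  if (cfg$coherence > 0 && !cfg$isolated &&
      cfg$figure_duration_chords + max(cfg$onset_jitter_chords) > cfg$n_chords)
    stop("invalid config: figure extends past the last chord")
  if (cfg$ramp_step < 0 || cfg$noise_gap_ms < 0 || cfg$ramp_ms < 0)
    stop("invalid config: ramp_step, ramp_ms and noise_gap_ms must be >= 0")
  if (cfg$coherence > 0 && cfg$ramp_step > 0 &&
      1 + cfg$ramp_step * (cfg$figure_duration_chords - 1) > n_pool)
    stop("invalid config: ramped figure cannot fit inside the pool")
  invisible(cfg)
}

#' @export
print.sfg_config <- function(x, ...) {
  cat(sprintf(
    "<sfg_config> %d chords x %g ms, coherence %d, duration %d%s%s%s\n",
    x$n_chords, x$chord_duration_ms, x$coherence, x$figure_duration_chords,
    if (x$ramp_step > 0) sprintf(", ramp step %d", x$ramp_step) else "",
    if (x$isolated) ", isolated" else "",
    if (x$noise_gap_ms > 0) sprintf(", %g ms noise gaps", x$noise_gap_ms) else ""
  ))
  invisible(x)
}
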