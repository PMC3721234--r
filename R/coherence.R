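# Temporal coherence stage: windowed, normalized cross-channel correlation of
# the complex rate-filter outputs. The off-diagonal maximum of the coherence
# matrix is the model's salience statistic; the figure-minus-ground
# difference of its Monte-Carlo average is the model response.

#' Windowed cross-channel coherence matrix
#'
#' For every channel pair (i, j) and window position t, computes the
#' magnitude of the windowed inner product of the complex rate-filter
#' outputs, normalized by the windowed channel powers (Cauchy-Schwarz, so
#' every entry lies in [0, 1]); the matrix entry is the maximum over window
#' positions. Windows span \code{window_cycles} cycles of the filter's
#' center rate and advance by \code{hop_fraction} of their length.
#' Near-silent windows (power below \code{eps} times the mean channel power)
#' contribute 0, never NaN.
#'
#' With \code{lambda_ref > 0} the normalization is regularized: entry
#' \eqn{|G_{ij}| / \sqrt{(G_{ii}+\lambda)(G_{jj}+\lambda)}} with
#' \eqn{\lambda} equal to \code{lambda_ref} times the mean windowed channel
#' power. The plain normalization (\code{lambda_ref = 0}) assigns
#' correlation 1 to any pair whose only activity is one shared chord --
#' tones of the same chord gate on and off together -- so the off-diagonal
#' maximum of a pure tone cloud saturates at 1 and carries no information.
#' The regularization acts as a detection threshold against the stimulus's
#' own mean power: only channel pairs that are both coherent and
#' well above that reference power approach 1, which is what lets a
#' sustained figure outgrow the ground. Entries remain within [0, 1].
#'
#' @param r An \code{sfg_rate_response}.
#' @param window_cycles Window length in cycles of the center rate.
#' @param hop_fraction Window advance as a fraction of the window length.
#' @param lambda_ref Regularization of the power normalization, as a
#'   multiple of the mean windowed channel power (0 = plain normalized
#'   correlation).
#' @param eps Relative power floor for silent-window handling.
#' @param warn Emit a warning when the window exceeds the signal (a single
#'   full-signal window is used instead).
#' @return An object of class \code{sfg_cohmat}: \code{values} (symmetric,
#'   unit diagonal, entries in [0, 1]), \code{rate_hz}, and
#'   \code{time_of_max} (frame index of the best window start per pair).
#' @export
coherence_matrix <- function(r, window_cycles = 4, hop_fraction = 0.5,
                             lambda_ref = 0, eps = 1e-8, warn = TRUE) {
  stopifnot(inherits(r, "sfg_rate_response"), window_cycles >= 1)
  u <- r$values
  k <- nrow(u)
  n <- ncol(u)
  if (k < 2) stop("invalid parameters: need at least 2 channels")
  w <- round(window_cycles / r$rate_hz * r$frame_rate_hz)
  if (w > n) {
    if (warn) warning("window longer than signal; using one full-signal window")
    w <- n
  }
  w <- max(2L, as.integer(w))
  hop <- max(1L, as.integer(round(w * hop_fraction)))
  starts <- unique(c(seq(1L, n - w + 1L, by = hop), n - w + 1L))
  mean_power <- mean(Mod(u)^2) * w
  floor_p <- eps * mean_power
  lam <- lambda_ref * mean_power
  best <- matrix(0, k, k)
  tmax <- matrix(NA_integer_, k, k)
  for (s0 in starts) {
    win <- u[, s0:(s0 + w - 1L), drop = FALSE]
    g <- win %*% Conj(t(win))
    p <- Re(diag(g))
    ok <- p > floor_p
    denom <- sqrt(outer(p + lam, p + lam))
    cm <- matrix(0, k, k)
    cm[ok, ok] <- pmin(Mod(g[ok, ok]) / denom[ok, ok], 1)
    cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]  # exact symmetry
    upd <- cm > best
    tmax[upd] <- s0
    best[upd] <- cm[upd]
  }
  diag(best) <- 1
  structure(list(values = best, rate_hz = r$rate_hz, time_of_max = tmax,
                 window_frames = w),
            class = "sfg_cohmat")
}

#' Maximum off-diagonal coherence
#'
#' The model's salience statistic: the largest coherence-matrix entry over
#' channel pairs more than \code{exclusion_span} channels apart. Adjacent
#' channels are trivially coherent through filter overlap, so a small
#' exclusion span keeps the statistic informative.
#'
#' @param m An \code{sfg_cohmat} (or a plain symmetric matrix).
#' @param exclusion_span Pairs with |i - j| <= exclusion_span are ignored
#'   (default 2).
#' @return The maximum admissible entry (scalar).
#' @export
max_cross_correlation <- function(m, exclusion_span = 2) {
  v <- if (inherits(m, "sfg_cohmat")) m$values else as.matrix(m)
  k <- nrow(v)
  if (is.null(k) || k < 2 || ncol(v) != k)
    stop("invalid parameters: need a square matrix of size >= 2")
  if (exclusion_span < 0) stop("invalid parameters: exclusion_span must be >= 0")
  d <- abs(row(v) - col(v))
  if (!any(d > exclusion_span))
    stop("invalid parameters: exclusion span leaves no admissible pairs")
  max(v[d > exclusion_span])
}

#' Model configuration for the temporal coherence analysis
#'
#' @param rates_hz Modulation rates at which coherence is evaluated
#'   (2.5/5/10/20 Hz for the 50 ms-chord designs; 5/10/20/40 Hz for 25 ms
#'   chords; 3.33 Hz is added for the long-noise variant).
#' @param scale_cyc_per_oct Spectral scale applied before rate filtering
#'   (8 cycles/octave; 4 for the steep ramped-figure variant). \code{NULL} or
#'   0 disables scale filtering.
#' @param n_iter Monte-Carlo iterations per condition (100 by default at
#'   desk scale; 500 reproduces the full protocol).
#' @param window_cycles Coherence window in cycles of each rate (default 4,
#'   matching the rate-kernel support so a window never resolves less than
#'   the filter's own impulse response).
#' @param exclusion_span Channel-adjacency exclusion for the maximum
#'   (default 2).
#' @param hop_fraction Coherence window advance (default 0.5, half-overlap).
#' @param lambda_ref Regularization of the coherence normalization (see
#'   \code{\link{coherence_matrix}}); the model chain defaults to 1 (mean
#'   channel power), which makes the off-diagonal maximum sensitive to
#'   sustained, above-reference coherent activity instead of saturating on
#'   same-chord tone pairs.
#' @param q_rate,kernel_cycles Rate-filter quality factor and kernel length.
#' @param frontend A \code{\link{frontend_config}}.
#' @return An object of class \code{sfg_model_config}.
#' @export
model_config <- function(rates_hz = c(2.5, 5, 10, 20), scale_cyc_per_oct = 8,
                         n_iter = 100, window_cycles = 4, exclusion_span = 2,
                         hop_fraction = 0.5, lambda_ref = 1, q_rate = 1,
                         kernel_cycles = 4, frontend = frontend_config()) {
  stopifnot(length(rates_hz) >= 1, all(rates_hz > 0), n_iter >= 1)
  if (any(rates_hz * 4 > frontend$frame_rate_hz))
    stop("invalid parameters: a rate exceeds frame_rate / 4")
  structure(
    list(rates_hz = sort(rates_hz), scale_cyc_per_oct = scale_cyc_per_oct,
         n_iter = as.integer(n_iter), window_cycles = window_cycles,
         exclusion_span = exclusion_span, hop_fraction = hop_fraction,
         lambda_ref = lambda_ref, q_rate = q_rate,
         kernel_cycles = kernel_cycles, frontend = frontend),
    class = "sfg_model_config"
  )
}

#' Per-rate salience statistics of one waveform
#'
#' Runs the full model chain on a single stimulus: auditory spectrogram,
#' optional spectral-scale filtering, then for every configured rate the
#' constant-Q rate filter, the windowed coherence matrix and its
#' off-diagonal maximum.
#'
#' @param w An \code{sfg_waveform}.
#' @param model An \code{\link{model_config}}.
#' @param warn Forwarded to \code{\link{coherence_matrix}}.
#' @return Named numeric vector of maxima, one per rate.
#' @export
stimulus_max_coherence <- function(w, model = model_config(), warn = TRUE) {
  s <- compute_spectrogram(w, model$frontend)
  if (!is.null(model$scale_cyc_per_oct) && model$scale_cyc_per_oct > 0) {
    # signed ripple contrast: the ripple phase carries the slow temporal
    # oscillation that a moving (ramped) figure imposes on each channel
    s <- apply_spectral_scale(s, model$scale_cyc_per_oct, output = "real")
  }
  out <- vapply(model$rates_hz, function(r) {
    rr <- rate_filter(s, r, q = model$q_rate, cycles = model$kernel_cycles)
    cm <- coherence_matrix(rr, window_cycles = model$window_cycles,
                           hop_fraction = model$hop_fraction,
                           lambda_ref = model$lambda_ref, warn = warn)
    max_cross_correlation(cm, model$exclusion_span)
  }, 0)
  names(out) <- format(model$rates_hz)
  out
}

#' Figure-minus-ground model response over a condition grid
#'
#' For every grid cell, generates \code{n_iter} figure-present and
#' \code{n_iter} matched figure-absent stimuli, runs the model chain on
#' each, and reports per rate the mean off-diagonal maximum for the two
#' classes and their difference (the model response). Figure and ground
#' trials of an iteration are generated from the same seed, so they share
#' the background draw, onset and window (the matched-pair protocol): the
#' class means are unchanged in expectation while the Monte-Carlo noise of
#' their difference is much reduced. Coherence-0 cells (ground vs ground)
#' use independent draws instead, since a shared seed would make the two
#' stimuli identical.
#'
#' @param grid Data frame with columns \code{coherence} and \code{duration}
#'   (chords); an optional \code{noise_gap_ms} column overrides the config.
#' @param config Base \code{\link{sfg_config}} shared by all cells.
#' @param model An \code{\link{model_config}}.
#' @param window \code{"full"} analyzes the whole stimulus; \code{"figure"}
#'   analyzes only the figure window (with its interleaved noise, if any).
#' @param seed Base integer seed; each trial uses a distinct derived seed.
#' @return Data frame with one row per (cell, rate): condition columns,
#'   \code{rate_hz}, \code{mean_max_figure}, \code{mean_max_ground},
#'   \code{delta}, \code{se_delta}, \code{n_iter}, \code{seed}.
#' @export
model_response <- function(grid, config = sfg_config(), model = model_config(),
                           window = c("full", "figure"), seed = 1) {
  window <- match.arg(window)
  stopifnot(is.data.frame(grid), all(c("coherence", "duration") %in% names(grid)))
  out <- vector("list", nrow(grid))
  trial_counter <- 0L
  for (i in seq_len(nrow(grid))) {
    cfg <- sfg_config_modify(
      config,
      coherence = as.integer(grid$coherence[i]),
      figure_duration_chords = as.integer(grid$duration[i]),
      noise_gap_ms = if ("noise_gap_ms" %in% names(grid))
        grid$noise_gap_ms[i] else config$noise_gap_ms
    )
    fig <- matrix(0, model$n_iter, length(model$rates_hz))
    gnd <- matrix(0, model$n_iter, length(model$rates_hz))
    for (it in seq_len(model$n_iter)) {
      s_fig <- seed + trial_counter
      s_gnd <- if (cfg$coherence > 0) s_fig else s_fig + 1L
      fig[it, ] <- model_trial_maxima(cfg, TRUE, window, model, s_fig,
                                      warn = it == 1)
      gnd[it, ] <- model_trial_maxima(cfg, FALSE, window, model, s_gnd,
                                      warn = FALSE)
      trial_counter <- trial_counter + 2L
    }
    mf <- colMeans(fig)
    mg <- colMeans(gnd)
    # standard error of the mean per-iteration difference (valid for the
    # matched-pair protocol and, conservatively, for independent draws)
    se <- sqrt(apply(fig - gnd, 2, stats::var) / model$n_iter)
    out[[i]] <- data.frame(
      coherence = grid$coherence[i], duration = grid$duration[i],
      noise_gap_ms = cfg$noise_gap_ms, rate_hz = model$rates_hz,
      mean_max_figure = mf, mean_max_ground = mg, delta = mf - mg,
      se_delta = se, n_iter = model$n_iter, seed = seed
    )
  }
  do.call(rbind, out)
}

model_trial_maxima <- function(cfg, figure_present, window, model, seed,
                               warn = FALSE) {
  if (cfg$coherence > 0) {
    cg <- sample_sfg_trial(cfg, figure_present = figure_present, seed = seed)
    if (window == "figure" && !cfg$isolated) {
      onset <- if (figure_present) cg$figure_onset_chord else cg$control_onset_chord
      dur <- if (figure_present) cfg$figure_duration_chords else
        cg$control_duration_chords
      cg <- trim_chordgram(cg, onset, onset + dur - 1L)
    }
  } else {
    cg <- sample_chordgram(cfg, seed = seed)
    if (window == "figure") {
      onset <- draw_figure_onset(cfg)
      dur <- max(1L, cfg$figure_duration_chords)
      cg <- trim_chordgram(cg, onset, onset + dur - 1L)
    }
  }
  w <- render_waveform(cg, cfg)
  stimulus_max_coherence(w, model, warn = warn)
}

#' Rate with the largest mean model response
#'
#' Aggregates the model response across all rows of a
#' \code{\link{model_response}} table and returns the rate maximizing the
#' mean delta; ties break toward the lower rate.
#'
#' @param responses A model-response data frame.
#' @return The best rate in Hz (scalar).
#' @export
best_rate <- function(responses) {
  if (!is.data.frame(responses) || nrow(responses) == 0 ||
      !all(c("rate_hz", "delta") %in% names(responses)))
    stop("invalid parameters: need a non-empty model-response table")
  agg <- stats::aggregate(delta ~ rate_hz, data = responses, FUN = mean)
  agg <- agg[order(agg$rate_hz), ]
  agg$rate_hz[which.max(agg$delta)]
}
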