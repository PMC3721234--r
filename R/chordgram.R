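# Symbolic stimulus representation: per-chord sets of pool indices with a
# background / figure / control label. The chordgram is the ground truth for
# every trial; rendering to a waveform is a separate, deterministic step.

resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

new_chordgram <- function(chords, pool, chord_duration_ms,
                          figure_onset_chord = NA_integer_,
                          figure_indices = NULL, seed = NULL) {
  structure(
    list(
      chords = chords,
      figure_onset_chord = figure_onset_chord,
      figure_indices = figure_indices,
      figure_frequencies = if (is.null(figure_indices)) NULL else
        pool$frequencies[figure_indices],
      chord_duration_ms = chord_duration_ms,
      pool = pool, seed = seed
    ),
    class = "sfg_chordgram"
  )
}

#' Number of chords in a chordgram
#' @param cg An \code{sfg_chordgram}.
#' @return Integer chord count.
#' @export
n_chords <- function(cg) length(cg$chords)

chord_components <- function(chord) {
  c(chord$background, chord$figure, chord$control)
}

#' Sample a stochastic figure-ground chordgram
#'
#' Draws the random tone-cloud background (a uniform number of components per
#' chord, each a uniform draw without replacement from the frequency pool)
#' and, when \code{config$coherence > 0}, embeds a repeating figure at an
#' onset drawn uniformly from the configured jitter range.
#'
#' @param config An \code{\link{sfg_config}}.
#' @param seed Integer seed for the trial's random stream (default
#'   \code{config$seed}; \code{NULL} uses the current RNG state).
#' @return An \code{sfg_chordgram}.
#' @export
sample_chordgram <- function(config, seed = config$seed) {
  validate_sfg_config(config)
  if (!is.null(seed)) set.seed(seed)
  n_pool <- length(config$pool$frequencies)
  counts <- resample(config$components_min:config$components_max,
                     size = config$n_chords, replace = TRUE)
  chords <- lapply(counts, function(m) {
    list(background = sort(sample.int(n_pool, m)),
         figure = integer(0), control = integer(0))
  })
  cg <- new_chordgram(chords, config$pool, config$chord_duration_ms,
                      seed = seed)
  if (config$coherence > 0) {
    onset <- draw_figure_onset(config)
    fig <- draw_figure_indices(config)
    cg <- embed_figure(cg, fig, onset, config$figure_duration_chords,
                       config$ramp_step)
    if (config$isolated) {
      cg <- trim_chordgram(cg, onset, onset + config$figure_duration_chords - 1)
    }
  }
  cg
}

draw_figure_onset <- function(config) {
  # jitter counts chords preceding the figure; onset is the first figure chord
  resample(seq(config$onset_jitter_chords[1], config$onset_jitter_chords[2])) + 1L
}

draw_figure_indices <- function(config) {
  n_pool <- length(config$pool$frequencies)
  top <- n_pool - config$ramp_step * (config$figure_duration_chords - 1L)
  if (top < config$coherence)
    stop("invalid parameters: ramped figure cannot fit inside the pool")
  sort(sample.int(top, config$coherence))
}

#' Embed a repeating figure into a chordgram
#'
#' Adds the figure components on top of the already-drawn background (the
#' figure is additive). With \code{ramp_step = 0} the same component set
#' repeats on every figure chord; with \code{ramp_step = s > 0} every index
#' increases by \code{s} pool steps per chord. A pool frequency appears at
#' most once per chord: a background component that collides with a figure
#' component is redrawn from the unused indices, so the coherence count and
#' the per-chord totals are both preserved exactly.
#'
#' @param cg An \code{sfg_chordgram}.
#' @param figure_indices Distinct pool indices of the figure components on
#'   its first chord.
#' @param onset 1-based index of the first figure chord.
#' @param duration Number of consecutive figure chords.
#' @param ramp_step Pool steps added per chord (0 = static figure).
#' @return The chordgram with figure components and metadata filled in.
#' @export
embed_figure <- function(cg, figure_indices, onset, duration, ramp_step = 0) {
  stopifnot(inherits(cg, "sfg_chordgram"))
  n_pool <- length(cg$pool$frequencies)
  figure_indices <- as.integer(figure_indices)
  if (anyDuplicated(figure_indices) || any(figure_indices < 1))
    stop("invalid parameters: figure indices must be distinct pool indices")
  if (onset < 1 || onset + duration - 1 > n_chords(cg))
    stop("invalid parameters: figure extends past the last chord")
  if (max(figure_indices) + ramp_step * (duration - 1) > n_pool)
    stop("invalid parameters: ramped figure exceeds the top of the pool")
  for (k in seq_len(duration) - 1L) {
    idx <- figure_indices + k * as.integer(ramp_step)
    j <- onset + k
    bg <- cg$chords[[j]]$background
    hit <- bg %in% idx
    if (any(hit)) {
      free <- setdiff(seq_len(n_pool), union(bg, idx))
      bg[hit] <- resample(free, size = sum(hit))
      cg$chords[[j]]$background <- sort(bg)
    }
    cg$chords[[j]]$figure <- idx
  }
  cg$figure_onset_chord <- as.integer(onset)
  cg$figure_indices <- figure_indices
  cg$figure_frequencies <- cg$pool$frequencies[figure_indices]
  cg
}

#' Embed incoherent control components into a figure-absent chordgram
#'
#' Figure-absent trials receive the same number of extra components per chord
#' as a figure trial would, but the added set is redrawn on every chord so no
#' coherent pattern forms. This matches the per-chord component counts (and
#' hence energy statistics) of the figure trials.
#'
#' @param cg A figure-absent \code{sfg_chordgram}.
#' @param n_components Components added per chord (a figure block's coherence).
#' @param onset 1-based index of the first control chord.
#' @param duration Number of consecutive control chords; values outside the
#'   2--7 range used in the experiments trigger a warning.
#' @return The chordgram with control components added.
#' @export
embed_control <- function(cg, n_components, onset, duration) {
  stopifnot(inherits(cg, "sfg_chordgram"))
  if (!is.na(cg$figure_onset_chord))
    stop("embed_control requires a figure-absent chordgram")
  if (n_components == 0) return(cg)
  if (duration < 2 || duration > 7)
    warning("control duration outside the 2-7 chord range of the designs")
  if (onset < 1 || onset + duration - 1 > n_chords(cg))
    stop("invalid parameters: control window extends past the last chord")
  n_pool <- length(cg$pool$frequencies)
  prev <- NULL
  for (j in onset:(onset + duration - 1)) {
    free <- setdiff(seq_len(n_pool), cg$chords[[j]]$background)
    if (length(free) < n_components)
      stop("invalid parameters: not enough free pool indices for controls")
    add <- sort(resample(free, size = n_components))
    while (!is.null(prev) && length(prev) == length(add) && all(add == prev)) {
      add <- sort(resample(free, size = n_components))
    }
    cg$chords[[j]]$control <- add
    prev <- add
  }
  cg
}

#' Keep a contiguous chord window
#'
#' Used for isolated-figure stimuli and for the figure-only analysis window
#' of the model protocol.
#'
#' @param cg An \code{sfg_chordgram}.
#' @param from,to 1-based chord indices (inclusive).
#' @return The trimmed chordgram, with \code{figure_onset_chord} re-indexed.
#' @export
trim_chordgram <- function(cg, from, to) {
  stopifnot(from >= 1, to <= n_chords(cg), from <= to)
  cg$chords <- cg$chords[from:to]
  if (!is.na(cg$figure_onset_chord))
    cg$figure_onset_chord <- cg$figure_onset_chord - as.integer(from) + 1L
  cg
}

#' Sample a complete SFG trial (figure-present or matched figure-absent)
#'
#' Figure and ground trials generated from the same seed share the identical
#' background draw, figure onset and window duration; they differ only in
#' whether the extra components repeat (figure) or are redrawn every chord
#' (control). This matched protocol equates per-chord component counts
#' chord-for-chord, so the two classes differ only in temporal coherence.
#'
#' @param config An \code{\link{sfg_config}} with \code{coherence > 0}.
#' @param figure_present Logical; \code{FALSE} yields the matched control.
#' @param seed Integer seed (default \code{config$seed}).
#' @param matched_duration If \code{FALSE}, a figure-absent trial draws its
#'   control duration uniformly on 2--7 chords (the behavioural protocol)
#'   instead of reusing the figure duration.
#' @return An \code{sfg_chordgram}.
#' @export
sample_sfg_trial <- function(config, figure_present = TRUE,
                             seed = config$seed, matched_duration = TRUE) {
  validate_sfg_config(config)
  if (config$coherence < 1)
    stop("sample_sfg_trial needs coherence >= 1; use sample_chordgram for plain clouds")
  if (!is.null(seed)) set.seed(seed)
  base <- sfg_config_modify(config, coherence = 0L,
                            figure_duration_chords = 0L, isolated = FALSE)
  cg <- sample_chordgram(base, seed = NULL)
  onset <- draw_figure_onset(config)
  duration <- config$figure_duration_chords
  if (figure_present) {
    fig <- draw_figure_indices(config)
    cg <- embed_figure(cg, fig, onset, duration, config$ramp_step)
  } else {
    if (!matched_duration) duration <- resample(2:7)
    cg <- suppressWarnings(
      embed_control(cg, config$coherence, onset, duration)
    )
    cg$control_onset_chord <- as.integer(onset)
    cg$control_duration_chords <- as.integer(duration)
  }
  if (config$isolated) cg <- trim_chordgram(cg, onset, onset + duration - 1)
  cg$seed <- seed
  cg
}

sfg_config_modify <- function(config, ...) {
  repl <- list(...)
  for (nm in names(repl)) config[[nm]] <- repl[[nm]]
  validate_sfg_config(config)
  config
}

#' Generate an AXB triplet
#'
#' Three figure-present stimuli with mutually different backgrounds; X shares
#' its figure component set with exactly one flanker, and the other flanker
#' (the "odd" one) carries a different figure. The odd position is A or B
#' with equal probability.
#'
#' @param config An \code{\link{sfg_config}} with \code{coherence > 0}.
#' @param seed Integer seed (default \code{config$seed}).
#' @return A list with chordgrams \code{A}, \code{X}, \code{B} and
#'   \code{odd} (\code{"A"} or \code{"B"}).
#' @export
make_axb_triplet <- function(config, seed = config$seed) {
  validate_sfg_config(config)
  if (config$coherence < 1) stop("AXB triplets require coherence >= 1")
  if (!is.null(seed)) set.seed(seed)
  shared <- draw_figure_indices(config)
  odd_fig <- draw_figure_indices(config)
  while (length(odd_fig) == length(shared) && all(odd_fig == shared)) {
    odd_fig <- draw_figure_indices(config)
  }
  odd <- resample(c("A", "B"))
  base <- sfg_config_modify(config, coherence = 0L,
                            figure_duration_chords = 0L, isolated = FALSE)
  make_one <- function(fig) {
    cg <- sample_chordgram(base, seed = NULL)
    embed_figure(cg, fig, draw_figure_onset(config),
                 config$figure_duration_chords, config$ramp_step)
  }
  a <- make_one(if (odd == "A") odd_fig else shared)
  x <- make_one(shared)
  b <- make_one(if (odd == "B") odd_fig else shared)
  list(A = a, X = x, B = b, odd = odd)
}

#' @export
print.sfg_chordgram <- function(x, ...) {
  cat(sprintf(
    "<sfg_chordgram> %d chords x %g ms%s\n", n_chords(x), x$chord_duration_ms,
    if (!is.na(x$figure_onset_chord))
      sprintf(", figure (%d components) at chords %d+",
              length(x$figure_indices), x$figure_onset_chord)
    else ""
  ))
  invisible(x)
}

#' Tabulate a chordgram as a long data frame
#'
#' @param x An \code{sfg_chordgram}.
#' @param ... Unused.
#' @return A data frame with columns \code{chord}, \code{pool_index},
#'   \code{frequency_hz}, \code{label}.
#' @export
as.data.frame.sfg_chordgram <- function(x, ...) {
  rows <- lapply(seq_along(x$chords), function(j) {
    ch <- x$chords[[j]]
    idx <- c(ch$background, ch$figure, ch$control)
    lab <- rep(c("background", "figure", "control"),
               c(length(ch$background), length(ch$figure), length(ch$control)))
    data.frame(chord = j, pool_index = idx,
               frequency_hz = x$pool$frequencies[idx], label = lab)
  })
  do.call(rbind, rows)
}
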