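# Configuration-driven reproduction of the six experimental designs: chord
# timing, the coherence x duration grid, the modulation rates, the spectral
# scale and the analysis-window policy for each.

#' Names of the built-in experiment designs
#' @return Character vector of valid experiment names.
#' @export
experiment_names <- function() {
  c("exp1", "exp2", "exp3", "exp4a", "exp4b", "exp5", "exp6a", "exp6b")
}

#' Built-in experiment specification
#'
#' Returns the full design of one of the SFG experiments: the stimulus
#' configuration template, the coherence x duration grid, the modulation
#' rates the coherence model is run at, the spectral scale and the analysis
#' window policy (the whole stimulus for the two baseline designs, the
#' figure window only for the others).
#'
#' @param name One of \code{\link{experiment_names}()}.
#' @param n_iter Monte-Carlo iterations per grid cell carried in the spec.
#' @param seed Base seed carried in the spec.
#' @return An object of class \code{sfg_experiment}: \code{name},
#'   \code{config} (an \code{\link{sfg_config}} template), \code{grid},
#'   \code{rates_hz}, \code{scale_cyc_per_oct}, \code{window},
#'   \code{n_iter}, \code{seed}.
#' @export
experiment_spec <- function(name, n_iter = 100, seed = 1) {
  if (!name %in% experiment_names())
    stop("unknown experiment; valid names: ",
         paste(experiment_names(), collapse = ", "))
  rates50 <- c(2.5, 5, 10, 20)
  spec <- switch(
    name,
    exp1 = list(
      config = sfg_config(chord_duration_ms = 50, n_chords = 40),
      grid = expand.grid(coherence = c(1, 2, 4, 6, 8), duration = 2:7),
      rates_hz = rates50, scale = 8, window = "full"
    ),
    exp2 = list(
      # AXB identification; all stimuli carry a figure of coherence 6
      config = sfg_config(chord_duration_ms = 50, n_chords = 40,
                          coherence = 6, figure_duration_chords = 4),
      grid = expand.grid(coherence = 6, duration = c(4, 8, 12)),
      rates_hz = rates50, scale = 8, window = "full"
    ),
    exp3 = list(
      config = sfg_config(chord_duration_ms = 25, n_chords = 40),
      grid = expand.grid(coherence = c(2, 4, 6, 8), duration = 2:7),
      rates_hz = c(5, 10, 20, 40), scale = 8, window = "full"
    ),
    exp4a = list(
      config = sfg_config(chord_duration_ms = 50, n_chords = 40,
                          ramp_step = 2),
      grid = expand.grid(coherence = c(4, 6, 8), duration = c(5, 7, 9)),
      rates_hz = rates50, scale = 8, window = "figure"
    ),
    exp4b = list(
      config = sfg_config(chord_duration_ms = 50, n_chords = 40,
                          ramp_step = 5),
      grid = expand.grid(coherence = c(4, 6, 8), duration = c(5, 7, 9)),
      rates_hz = rates50, scale = 4, window = "figure"
    ),
    exp5 = list(
      config = sfg_config(chord_duration_ms = 50, n_chords = 40,
                          isolated = TRUE),
      grid = expand.grid(coherence = c(2, 4, 6, 8), duration = 3:7),
      rates_hz = rates50, scale = 8, window = "figure"
    ),
    exp6a = list(
      config = sfg_config(chord_duration_ms = 50, n_chords = 40,
                          noise_gap_ms = 50),
      grid = expand.grid(coherence = c(2, 4, 6, 8), duration = 3:7),
      rates_hz = rates50, scale = 8, window = "figure"
    ),
    exp6b = list(
      config = sfg_config(chord_duration_ms = 50, n_chords = 40,
                          noise_gap_ms = 50),
      grid = data.frame(coherence = 6, duration = 6,
                        noise_gap_ms = c(50, 100, 150, 200, 250, 300, 500)),
      rates_hz = c(2.5, 3.33, 5, 10, 20), scale = 8, window = "figure"
    )
  )
  structure(
    list(name = name, config = spec$config, grid = spec$grid,
         rates_hz = spec$rates_hz, scale_cyc_per_oct = spec$scale,
         window = spec$window, n_iter = as.integer(n_iter),
         seed = as.integer(seed)),
    class = "sfg_experiment"
  )
}

#' @export
print.sfg_experiment <- function(x, ...) {
  cat(sprintf(
    "<sfg_experiment> %s: %d grid cells, rates {%s} Hz, scale %g cyc/oct, %s window\n",
    x$name, nrow(x$grid), paste(x$rates_hz, collapse = ", "),
    x$scale_cyc_per_oct, x$window
  ))
  invisible(x)
}

#' Run the coherence model over an experiment grid
#'
#' Evaluates \code{\link{model_response}} on every grid cell of the design
#' and optionally writes the result table, example stimuli (WAV plus a JSON
#' sidecar with the seed, figure onset and per-chord component lists) and a
#' provenance record to \code{out_dir}.
#'
#' @param spec An \code{\link{experiment_spec}} (or an experiment name).
#' @param out_dir Optional output directory; created if missing.
#' @param n_example_wavs Example stimuli written per run (0 disables).
#' @param model Optional \code{\link{model_config}} overriding the spec's
#'   rates/scale/n_iter (advanced use).
#' @return The model-response data frame (invisibly carries the attribute
#'   \code{"experiment"}).
#' @export
run_experiment <- function(spec, out_dir = NULL, n_example_wavs = 0,
                           model = NULL) {
  if (is.character(spec)) spec <- experiment_spec(spec)
  stopifnot(inherits(spec, "sfg_experiment"))
  if (is.null(model)) {
    model <- model_config(rates_hz = spec$rates_hz,
                          scale_cyc_per_oct = spec$scale_cyc_per_oct,
                          n_iter = spec$n_iter)
  }
  res <- model_response(spec$grid, config = spec$config, model = model,
                        window = spec$window, seed = spec$seed)
  res <- cbind(experiment = spec$name, res)
  attr(res, "experiment") <- spec$name
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, paste0(spec$name, "_model.csv")),
                     row.names = FALSE)
    if (n_example_wavs > 0) export_example_stimuli(spec, out_dir, n_example_wavs)
    prov <- list(experiment = spec$name, seed = spec$seed,
                 n_iter = model$n_iter, rates_hz = model$rates_hz,
                 scale_cyc_per_oct = model$scale_cyc_per_oct,
                 window = spec$window,
                 grid = spec$grid)
    jsonlite::write_json(prov, file.path(out_dir,
                                         paste0(spec$name, "_provenance.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

export_example_stimuli <- function(spec, out_dir, n) {
  cell <- spec$grid[nrow(spec$grid), ]
  cfg <- sfg_config_modify(
    spec$config,
    coherence = max(1L, as.integer(cell$coherence)),
    figure_duration_chords = as.integer(cell$duration),
    noise_gap_ms = if ("noise_gap_ms" %in% names(cell)) cell$noise_gap_ms
                   else spec$config$noise_gap_ms
  )
  for (i in seq_len(n)) {
    s <- spec$seed + 7000L + i
    cg <- sample_sfg_trial(cfg, figure_present = TRUE, seed = s)
    w <- render_waveform(cg, cfg)
    stem <- file.path(out_dir, sprintf("%s_example_%02d", spec$name, i))
    write_wav(w, paste0(stem, ".wav"))
    write_stimulus_sidecar(cg, cfg, paste0(stem, ".json"))
  }
}

#' Write the JSON annotation sidecar of a stimulus
#'
#' @param cg An \code{sfg_chordgram}.
#' @param config The generating \code{\link{sfg_config}}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_stimulus_sidecar <- function(cg, config, path) {
  onset_ms <- if (is.na(cg$figure_onset_chord)) NULL else
    (cg$figure_onset_chord - 1) * cg$chord_duration_ms
  meta <- list(
    seed = cg$seed,
    chord_duration_ms = cg$chord_duration_ms,
    n_chords = n_chords(cg),
    coherence = config$coherence,
    figure_duration_chords = config$figure_duration_chords,
    ramp_step = config$ramp_step,
    noise_gap_ms = config$noise_gap_ms,
    figure_onset_chord = cg$figure_onset_chord,
    figure_onset_ms = onset_ms,
    figure_frequencies_hz = cg$figure_frequencies,
    chords = lapply(cg$chords, function(ch) {
      list(background = ch$background, figure = ch$figure,
           control = ch$control)
    })
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
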