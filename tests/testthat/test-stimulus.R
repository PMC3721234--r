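test_that("frequency pool matches the 1/24-octave grid", {
  pool <- build_frequency_pool()
  expect_length(pool$frequencies, 129)
  expect_equal(pool$frequencies[1], 179)
  expect_lte(max(pool$frequencies), 7246)
  ratios <- diff(log2(pool$frequencies))
  expect_equal(ratios, rep(1 / 24, 128), tolerance = 1e-9)
  # closed form: 24 steps above the base is exactly one octave
  expect_equal(pool$frequencies[25], 179 * 2, tolerance = 1e-12)

  degenerate <- build_frequency_pool(179, 1 / 24, 179)
  expect_equal(degenerate$frequencies, 179)

  expect_error(build_frequency_pool(-1, 1 / 24, 100), "invalid")
  expect_error(build_frequency_pool(200, 1 / 24, 100), "invalid")
  expect_error(build_frequency_pool(100, 0, 200), "invalid")
})

test_that("chordgram sampling respects counts, contiguity and figure identity", {
  cfg <- exp1_config(coherence = 6, duration = 7)
  cg <- sample_chordgram(cfg, seed = 42)
  expect_equal(n_chords(cg), 40)
  bg_counts <- vapply(cg$chords, function(ch) length(ch$background), 0L)
  expect_true(all(bg_counts >= 5 & bg_counts <= 15))
  fig_chords <- which(vapply(cg$chords, function(ch) length(ch$figure) > 0, NA))
  expect_length(fig_chords, 7)
  expect_equal(fig_chords, seq(min(fig_chords), min(fig_chords) + 6))
  fig_sets <- lapply(cg$chords[fig_chords], `[[`, "figure")
  expect_true(all(vapply(fig_sets, length, 0L) == 6))
  for (s in fig_sets) expect_equal(s, fig_sets[[1]])
  # a pool frequency appears at most once per chord
  for (ch in cg$chords) expect_false(anyDuplicated(
    c(ch$background, ch$figure, ch$control)) > 0)

  plain <- sample_chordgram(sfg_config(), seed = 1)
  expect_true(all(vapply(plain$chords, function(ch) length(ch$figure), 0L) == 0))
})

test_that("background component count is uniform on 5..15 (mean 10)", {
  cfg <- sfg_config()
  counts <- unlist(lapply(1:250, function(i) {
    vapply(sample_chordgram(cfg, seed = i)$chords,
           function(ch) length(ch$background), 0L)
  }))
  expect_length(counts, 10000)
  expect_equal(mean(counts), 10, tolerance = 0.1 / 10)
  expect_setequal(unique(counts), 5:15)
})

test_that("figure onsets are uniform on 15..20 chords before the figure", {
  cfg <- exp1_config()
  onsets <- vapply(1:5000, function(i)
    sample_chordgram(cfg, seed = i)$figure_onset_chord, 0L)
  expect_setequal(unique(onsets), 16:21)
  expect_gte(min(onsets - 1L) * 50, 750)  # earliest onset in ms
  p <- stats::chisq.test(table(onsets))$p.value
  expect_gt(p, 0.001)
})

test_that("ramped figures follow the arithmetic progression and stay in pool", {
  cfg <- exp1_config()
  cg <- sample_chordgram(sfg_config(), seed = 7)
  out <- embed_figure(cg, 10, onset = 5, duration = 3, ramp_step = 2)
  expect_equal(out$chords[[5]]$figure, 10L)
  expect_equal(out$chords[[6]]$figure, 12L)
  expect_equal(out$chords[[7]]$figure, 14L)

  # steepest design cell: every figure cell within pool bounds over many seeds
  steep <- sfg_config(coherence = 8, figure_duration_chords = 9, ramp_step = 5)
  for (i in 1:1000) {
    cg <- sample_chordgram(steep, seed = i)
    idx <- unlist(lapply(cg$chords, `[[`, "figure"))
    expect_true(all(idx >= 1 & idx <= 129))
    expect_length(idx, 72)
  }

  expect_error(embed_figure(cg, 128, 5, 3, ramp_step = 2), "invalid")
  expect_error(embed_figure(cg, c(3, 3), 5, 3), "invalid")
  expect_error(embed_figure(cg, 10, 39, 3), "invalid")
})

test_that("controls change chord to chord and match figure counts", {
  cfg <- exp1_config()
  cg <- sample_chordgram(sfg_config(), seed = 9)
  out <- embed_control(cg, 6, onset = 10, duration = 4)
  added <- lapply(out$chords[10:13], `[[`, "control")
  expect_true(all(vapply(added, length, 0L) == 6))
  for (k in 2:4) expect_false(identical(added[[k]], added[[k - 1]]))

  expect_identical(embed_control(cg, 0, 10, 4), cg)
  expect_warning(embed_control(cg, 3, 10, 9), "2-7")

  # matched figure/ground pairs: identical per-chord totals, chord for chord
  for (i in 1:200) {
    fig <- sample_sfg_trial(cfg, TRUE, seed = i)
    gnd <- sample_sfg_trial(cfg, FALSE, seed = i)
    nf <- vapply(fig$chords, function(ch) length(c(ch$background, ch$figure,
                                                   ch$control)), 0L)
    ng <- vapply(gnd$chords, function(ch) length(c(ch$background, ch$figure,
                                                   ch$control)), 0L)
    expect_equal(nf, ng)
  }
})

test_that("every component frequency belongs to the pool", {
  cfg <- exp1_config(coherence = 8, duration = 7)
  cg <- sample_sfg_trial(cfg, TRUE, seed = 5)
  tab <- as.data.frame(cg)
  expect_true(all(tab$frequency_hz %in% cg$pool$frequencies))
  expect_true(all(tab$pool_index >= 1 & tab$pool_index <= 129))
})

test_that("sampling is deterministic given seed and config", {
  cfg <- exp1_config(coherence = 4, duration = 5, seed = 77)
  a <- sample_sfg_trial(cfg)
  b <- sample_sfg_trial(cfg)
  expect_identical(a, b)
  wa <- render_waveform(a, cfg, seed = 3)
  wb <- render_waveform(b, cfg, seed = 3)
  expect_identical(wa$samples, wb$samples)
})

test_that("AXB triplets share one figure and differ in backgrounds", {
  cfg <- exp1_config(coherence = 6, duration = 8)
  tri <- make_axb_triplet(cfg, seed = 21)
  figs <- lapply(tri[c("A", "X", "B")], `[[`, "figure_indices")
  match_a <- identical(figs$A, figs$X)
  match_b <- identical(figs$B, figs$X)
  expect_true(xor(match_a, match_b))
  expect_equal(tri$odd, if (match_a) "B" else "A")
  # matching figures identical on every figure chord
  keep <- if (match_a) tri$A else tri$B
  fx <- lapply(Filter(function(ch) length(ch$figure) > 0, tri$X$chords),
               `[[`, "figure")
  fk <- lapply(Filter(function(ch) length(ch$figure) > 0, keep$chords),
               `[[`, "figure")
  expect_identical(unique(fx), unique(fk))
  # backgrounds mutually different
  expect_false(identical(tri$A$chords[[1]]$background,
                         tri$X$chords[[1]]$background))

  odd <- vapply(1:500, function(i) make_axb_triplet(cfg, seed = i)$odd, "")
  expect_gt(mean(odd == "A"), 0.4)
  expect_lt(mean(odd == "A"), 0.6)
})

test_that("rendered waveforms have exact durations and bounded amplitude", {
  cfg <- exp1_config(coherence = 6, duration = 7)
  cg <- sample_sfg_trial(cfg, seed = 2)
  w <- render_waveform(cg, cfg)
  expect_length(w$samples, 88200)  # 40 chords x 50 ms at 44.1 kHz
  expect_lte(max(abs(w$samples)), 1)
  expect_equal(max(abs(w$samples)), 1)

  cfg25 <- sfg_config(chord_duration_ms = 25, n_chords = 40, coherence = 6,
                      figure_duration_chords = 7)
  w25 <- render_waveform(sample_sfg_trial(cfg25, seed = 2), cfg25)
  expect_length(w25$samples, 44100)  # 1000 ms

  iso <- sfg_config(coherence = 6, figure_duration_chords = 7, isolated = TRUE)
  wi <- render_waveform(sample_sfg_trial(iso, seed = 2), iso)
  expect_length(wi$samples, 15435)  # 350 ms

  # silence renders to zeros of the exact length
  empty <- sample_chordgram(sfg_config(components_min = 0, components_max = 0),
                            seed = 1)
  we <- render_waveform(empty, sfg_config())
  expect_length(we$samples, 88200)
  expect_true(all(we$samples == 0))
})

test_that("a single pure tone renders to a spectral line at its frequency", {
  cfg <- sfg_config(n_chords = 1, components_min = 1, components_max = 1,
                    ramp_ms = 10)
  pool <- cfg$pool
  target <- which.min(abs(pool$frequencies - 1000))
  cg <- sample_chordgram(cfg, seed = 1)
  cg$chords[[1]]$background <- target
  w <- render_waveform(cg, cfg)
  spec <- Mod(stats::fft(w$samples))
  half <- seq_len(length(spec) %/% 2)
  peak_hz <- (which.max(spec[half]) - 1) * cfg$sample_rate_hz / length(spec)
  expect_lt(abs(peak_hz - pool$frequencies[target]), 25)
})

test_that("interleaved noise bursts sit 12 dB above the chord level", {
  cfg <- sfg_config(coherence = 8, figure_duration_chords = 7,
                    noise_gap_ms = 50)
  lv <- vapply(1:20, function(i) {
    noise_chord_level_db(render_waveform(sample_sfg_trial(cfg, seed = i), cfg,
                                         seed = i + 5000))
  }, 0)
  expect_equal(mean(lv), 12, tolerance = 0.5 / 12)
  # duration accounting includes the noise segments exactly
  w <- render_waveform(sample_sfg_trial(cfg, seed = 1), cfg)
  expect_length(w$samples, 40 * (2205 + 2205))
})

test_that("WAV files round-trip through the PCM writer", {
  cfg <- sfg_config(n_chords = 4, coherence = 2, figure_duration_chords = 2,
                    onset_jitter_chords = c(1, 2))
  w <- render_waveform(sample_sfg_trial(cfg, seed = 3), cfg)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate_hz, 44100)
  expect_equal(back$samples, w$samples, tolerance = 1e-4)
  expect_equal(file.size(path), 44 + 2 * length(w$samples))
})
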