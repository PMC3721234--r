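test_that("an exact channel copy gives coherence 1 and matrices are symmetric", {
  set.seed(21)
  u <- matrix(complex(real = rnorm(3 * 800), imaginary = rnorm(3 * 800)),
              3, 800)
  u[2, ] <- u[1, ]
  cm <- coherence_matrix(toy_rate_response(u, rate_hz = 10), warn = FALSE)
  expect_equal(cm$values[1, 2], 1)
  expect_identical(cm$values, t(cm$values))
  expect_true(all(cm$values >= 0 & cm$values <= 1))
  expect_equal(diag(cm$values), rep(1, 3))
  expect_equal(cm$rate_hz, 10)
  # the time of the best window is recorded as a valid start frame
  off <- cm$time_of_max[upper.tri(cm$time_of_max)]
  expect_true(all(off >= 1 & off <= 800 - cm$window_frames + 1))
})

test_that("coherence matches a brute-force windowed-correlation oracle", {
  brute <- function(u, rate, fr, wc, hop_frac, lam_ref) {
    k <- nrow(u); n <- ncol(u)
    w <- max(2L, as.integer(round(wc / rate * fr)))
    hop <- max(1L, as.integer(round(w * hop_frac)))
    starts <- unique(c(seq(1L, n - w + 1L, by = hop), n - w + 1L))
    lam <- lam_ref * mean(Mod(u)^2) * w
    out <- diag(1, k)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      best <- 0
      for (s0 in starts) {
        idx <- s0:(s0 + w - 1)
        num <- Mod(sum(u[i, idx] * Conj(u[j, idx])))
        den <- sqrt((sum(Mod(u[i, idx])^2) + lam) *
                    (sum(Mod(u[j, idx])^2) + lam))
        best <- max(best, num / den)
      }
      out[i, j] <- out[j, i] <- best
    }
    out
  }
  set.seed(22)
  for (lam_ref in c(0, 1)) {
    u <- matrix(complex(real = rnorm(3 * 400), imaginary = rnorm(3 * 400)),
                3, 400)
    cm <- coherence_matrix(toy_rate_response(u, rate_hz = 10), lambda_ref = lam_ref,
                           warn = FALSE)
    expect_equal(cm$values, brute(u, 10, 400, 4, 0.5, lam_ref),
                 tolerance = 1e-10)
  }
})

test_that("independent noise envelopes decorrelate over a full-signal window", {
  # 2 s of independent envelope noise at the 20 Hz rate, correlated over one
  # whole-signal window (40 cycles)
  set.seed(23)
  fr <- 400
  vals <- replicate(400, {
    env <- matrix(abs(rnorm(2 * 800)), 2, 800)
    s <- sfgmodel:::new_spectrogram(env, c(1000, 2000), fr)
    rr <- rate_filter(s, 20)
    coherence_matrix(rr, window_cycles = 40, warn = FALSE)$values[1, 2]
  })
  expect_gte(mean(vals < 0.5), 0.95)
})

test_that("silent channels yield zero coherence, never NaN", {
  set.seed(24)
  u <- matrix(complex(real = rnorm(3 * 400), imaginary = rnorm(3 * 400)),
              3, 400)
  u[3, ] <- 0
  cm <- coherence_matrix(toy_rate_response(u, rate_hz = 10), warn = FALSE)
  expect_false(anyNA(cm$values))
  expect_equal(cm$values[1, 3], 0)
  expect_equal(cm$values[2, 3], 0)
})

test_that("a window longer than the signal degrades to one window with warning", {
  set.seed(25)
  u <- matrix(complex(real = rnorm(2 * 50), imaginary = rnorm(2 * 50)), 2, 50)
  expect_warning(coherence_matrix(toy_rate_response(u, rate_hz = 2.5)),
                 "window longer")
})

test_that("max_cross_correlation scans admissible off-diagonal pairs", {
  expect_equal(max_cross_correlation(diag(5), exclusion_span = 0), 0)
  m <- diag(5)
  m[1, 4] <- m[4, 1] <- 0.8
  expect_equal(max_cross_correlation(m, exclusion_span = 2), 0.8)
  set.seed(26)
  r <- matrix(runif(100), 10, 10)
  r <- (r + t(r)) / 2
  for (span in 0:3) {
    d <- abs(row(r) - col(r))
    expect_equal(max_cross_correlation(r, span), max(r[d > span]))
  }
  expect_error(max_cross_correlation(matrix(1, 1, 1)), "invalid")
  expect_error(max_cross_correlation(diag(3), exclusion_span = 5), "invalid")
})

test_that("model response is deterministic and near zero without a figure", {
  cfg <- sfg_config(n_chords = 12, onset_jitter_chords = c(2, 4))
  mc <- model_config(rates_hz = c(10, 20), n_iter = 2)
  g <- data.frame(coherence = 0, duration = 4)
  a <- model_response(g, cfg, mc, window = "full", seed = 31)
  b <- model_response(g, cfg, mc, window = "full", seed = 31)
  expect_identical(a, b)
  expect_equal(a$delta, a$mean_max_figure - a$mean_max_ground)
})

test_that("best_rate picks the argmax delta and breaks ties downward", {
  tbl <- data.frame(rate_hz = c(2.5, 5, 10, 20), delta = c(0.1, 0.2, 0.6, 0.3))
  expect_equal(best_rate(tbl), 10)
  tie <- data.frame(rate_hz = c(5, 10), delta = c(0.4, 0.4))
  expect_equal(best_rate(tie), 5)
  single <- data.frame(rate_hz = 10, delta = 0.2)
  expect_equal(best_rate(single), 10)
  expect_error(best_rate(data.frame()), "invalid")
})

test_that("the figure's coherent channels drive the model statistic", {
  # one figure trial vs its matched ground: with a strong figure the per-rate
  # maxima at the chord rate should not be smaller for the figure stimulus
  cfg <- sfg_config(coherence = 8, figure_duration_chords = 7, isolated = TRUE)
  mc <- model_config(rates_hz = 20, n_iter = 1)
  one <- function(present, seed) {
    w <- render_waveform(sample_sfg_trial(cfg, present, seed = seed), cfg)
    stimulus_max_coherence(w, mc, warn = FALSE)
  }
  f <- vapply(1:15, function(i) one(TRUE, 40 + i), 0)
  g <- vapply(1:15, function(i) one(FALSE, 140 + i), 0)
  expect_gt(mean(f), mean(g))
})
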