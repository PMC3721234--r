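test_that("yes/no d-prime matches an independent normal-quantile oracle", {
  skip_if_not_installed("pracma")
  # equal rates: no sensitivity
  expect_equal(d_prime_yesno(10, 10, 10, 10)$d_prime, 0)

  r <- d_prime_yesno(93, 7, 5, 95)
  hr <- (93 + 0.5) / 101
  far <- (5 + 0.5) / 101
  expect_equal(r$hit_rate, hr)
  expect_equal(r$fa_rate, far)
  expect_equal(r$d_prime, z_oracle(hr) - z_oracle(far), tolerance = 1e-9)

  # ceiling performance stays finite through the log-linear correction
  perfect <- d_prime_yesno(25, 0, 0, 25)
  expect_true(is.finite(perfect$d_prime))
  expect_equal(perfect$hit_rate, 25.5 / 26)

  expect_error(d_prime_yesno(-1, 0, 0, 5), "invalid")
  expect_error(d_prime_yesno(0, 0, 2, 3), "invalid")
  expect_error(d_prime_yesno(25, 0, 0, 25, correction = FALSE), "correction")
})

test_that("d-prime is antisymmetric and the correction vanishes with n", {
  a <- d_prime_yesno(80, 20, 30, 70)
  b <- d_prime_yesno(30, 70, 80, 20)
  expect_equal(a$d_prime, -b$d_prime)
  # fixed rates 0.8 / 0.3, growing n
  n <- 1e4
  corrected <- d_prime_yesno(0.8 * n, 0.2 * n, 0.3 * n, 0.7 * n)$d_prime
  uncorrected <- stats::qnorm(0.8) - stats::qnorm(0.3)
  expect_lt(abs(corrected - uncorrected), 0.01)
})

test_that("AXB d-prime follows the differencing approximation", {
  skip_if_not_installed("pracma")
  expect_equal(d_prime_axb(0.5, 180)$d_prime, sqrt(2) *
                 stats::qnorm((90 + 0.5) / 181))
  r <- d_prime_axb(0.75, 180)
  expect_equal(r$d_prime, sqrt(2) * z_oracle((135 + 0.5) / 181),
               tolerance = 1e-9)
  pcs <- seq(0.1, 0.9, by = 0.1)
  dps <- vapply(pcs, function(p) d_prime_axb(p, 100)$d_prime, 0)
  expect_true(all(diff(dps) > 0))
  expect_error(d_prime_axb(1.2, 10), "invalid")
})

test_that("condition summaries aggregate subjects with closed-form mean/SEM", {
  set.seed(51)
  subjects <- paste0("s", 1:9)
  grid <- expand.grid(coherence = c(4, 8), duration = c(3, 7))
  trials <- do.call(rbind, lapply(subjects, function(su) {
    do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
      present <- rep(c(TRUE, FALSE), each = 25)
      p_yes <- ifelse(present, 0.6 + 0.04 * grid$coherence[g], 0.2)
      data.frame(subject = su, coherence = grid$coherence[g],
                 duration = grid$duration[g], figure_present = present,
                 response = stats::runif(50) < p_yes)
    }))
  }))
  out <- summarize_conditions(trials)
  expect_equal(nrow(out), 4)
  # direct formula oracle on one cell
  cell <- out[out$coherence == 8 & out$duration == 7, ]
  dps <- vapply(subjects, function(su) {
    d <- trials[trials$subject == su & trials$coherence == 8 &
                  trials$duration == 7, ]
    h <- sum(d$figure_present & d$response)
    fa <- sum(!d$figure_present & d$response)
    d_prime_yesno(h, 25 - h, fa, 25 - fa)$d_prime
  }, 0)
  expect_equal(cell$mean_d_prime, mean(dps))
  expect_equal(cell$sem_d_prime, stats::sd(dps) / 3)
  expect_equal(cell$n_subjects, 9)

  # permutation invariance over subject order
  shuffled <- trials[sample(nrow(trials)), ]
  expect_equal(summarize_conditions(shuffled), out)

  single <- trials[trials$subject == "s1", ]
  expect_true(is.na(summarize_conditions(single)$sem_d_prime[1]))
  expect_error(summarize_conditions(trials[0, ]), "empty")
})
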