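# Signal-detection analysis: d' for yes/no figure detection and for the
# AXB identification task, with the log-linear correction (add 0.5 to every
# response cell) so ceiling-level hit rates yield finite sensitivity.

new_sensitivity_result <- function(hits, misses, false_alarms,
                                   correct_rejections, hit_rate, fa_rate,
                                   d_prime) {
  structure(
    list(hits = hits, misses = misses, false_alarms = false_alarms,
         correct_rejections = correct_rejections, hit_rate = hit_rate,
         fa_rate = fa_rate, d_prime = d_prime),
    class = "sfg_sensitivity"
  )
}

#' @export
print.sfg_sensitivity <- function(x, ...) {
  cat(sprintf("<sfg_sensitivity> d' = %.3f (hit rate %.3f, FA rate %.3f)\n",
              x$d_prime, x$hit_rate, x$fa_rate))
  invisible(x)
}

#' Yes/no sensitivity (d')
#'
#' Computes \eqn{d' = z(\mathrm{hit\ rate}) - z(\mathrm{FA\ rate})} from the
#' four response counts. The log-linear correction (0.5 added to every cell
#' before rates are formed) keeps rates strictly inside (0, 1), so d' is
#' finite even for perfect hit or zero false-alarm counts.
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts.
#' @param correction Apply the log-linear correction (default \code{TRUE}).
#' @return An \code{sfg_sensitivity} object.
#' @export
d_prime_yesno <- function(hits, misses, false_alarms, correct_rejections,
                          correction = TRUE) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("invalid parameters: counts must be non-negative integers")
  if (hits + misses == 0 || false_alarms + correct_rejections == 0)
    stop("invalid parameters: need at least one signal and one noise trial")
  a <- if (correction) 0.5 else 0
  hr <- (hits + a) / (hits + misses + 2 * a)
  far <- (false_alarms + a) / (false_alarms + correct_rejections + 2 * a)
  if (hr <= 0 || hr >= 1 || far <= 0 || far >= 1)
    stop("rates at 0 or 1; enable the correction for finite d'")
  new_sensitivity_result(hits, misses, false_alarms, correct_rejections,
                         hr, far, stats::qnorm(hr) - stats::qnorm(far))
}

#' AXB sensitivity (d')
#'
#' Maps proportion correct in the AXB identification task to d' through the
#' two-alternative differencing approximation
#' \eqn{d' = \sqrt{2}\, z(p_c)}, after the log-linear correction
#' \eqn{p_c \to (p_c n + 0.5) / (n + 1)}.
#'
#' @param proportion_correct Proportion of correct odd-one identifications,
#'   in [0, 1].
#' @param n_trials Number of trials behind the proportion.
#' @param correction Apply the log-linear correction (default \code{TRUE}).
#' @return An \code{sfg_sensitivity} object (count fields hold the implied
#'   correct/incorrect trial counts).
#' @export
d_prime_axb <- function(proportion_correct, n_trials, correction = TRUE) {
  if (proportion_correct < 0 || proportion_correct > 1 || n_trials < 1)
    stop("invalid parameters: need 0 <= pc <= 1 and n_trials >= 1")
  n_correct <- round(proportion_correct * n_trials)
  pc <- if (correction) (n_correct + 0.5) / (n_trials + 1)
        else n_correct / n_trials
  if (pc <= 0 || pc >= 1)
    stop("proportion at 0 or 1; enable the correction for finite d'")
  new_sensitivity_result(n_correct, n_trials - n_correct, NA, NA,
                         pc, NA, sqrt(2) * stats::qnorm(pc))
}

#' Per-condition sensitivity summary across subjects
#'
#' Computes d' per subject and condition from a long trial table, then the
#' group mean and the standard error of the mean (SEM) per condition.
#'
#' @param trials Data frame with columns \code{subject}, \code{coherence},
#'   \code{duration}, \code{figure_present} (logical) and \code{response}
#'   (logical "yes"), one row per trial.
#' @return Data frame with one row per (coherence, duration):
#'   \code{mean_d_prime}, \code{sem_d_prime} (\code{NA} for a single
#'   subject), \code{n_subjects}.
#' @export
summarize_conditions <- function(trials) {
  needed <- c("subject", "coherence", "duration", "figure_present", "response")
  if (!is.data.frame(trials) || !all(needed %in% names(trials)))
    stop("trials must contain columns ", paste(needed, collapse = ", "))
  if (nrow(trials) == 0) stop("empty trial table")
  per_subject <- do.call(rbind, lapply(
    split(trials, trials[c("coherence", "duration", "subject")], drop = TRUE),
    function(d) {
      h <- sum(d$figure_present & d$response)
      m <- sum(d$figure_present & !d$response)
      fa <- sum(!d$figure_present & d$response)
      cr <- sum(!d$figure_present & !d$response)
      dp <- d_prime_yesno(h, m, fa, cr)$d_prime
      data.frame(coherence = d$coherence[1], duration = d$duration[1],
                 subject = d$subject[1], d_prime = dp)
    }
  ))
  out <- do.call(rbind, lapply(
    split(per_subject, per_subject[c("coherence", "duration")], drop = TRUE),
    function(d) {
      n <- nrow(d)
      data.frame(
        coherence = d$coherence[1], duration = d$duration[1],
        mean_d_prime = mean(d$d_prime),
        sem_d_prime = if (n > 1) stats::sd(d$d_prime) / sqrt(n) else NA_real_,
        n_subjects = n
      )
    }
  ))
  rownames(out) <- NULL
  out[order(out$coherence, out$duration), ]
}
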