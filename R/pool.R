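#' Build the log-spaced frequency pool
#'
#' Constructs the fixed pool of candidate pure-tone frequencies from which
#' every chord component of an SFG stimulus is drawn: all frequencies
#' \code{f_min * 2^(k * step_octaves)} not exceeding \code{f_max}. With the
#' default arguments (179 Hz to 7246 Hz in 1/24-octave steps) the pool holds
#' 129 frequencies.
#'
#' @param f_min Lowest pool frequency in Hz (default 179).
#' @param step_octaves Spacing between adjacent pool members in octaves
#'   (default 1/24).
#' @param f_max Upper frequency bound in Hz (default 7246); the pool stops at
#'   the largest grid point not exceeding it.
#' @return An object of class \code{sfg_pool}: a list with elements
#'   \code{frequencies} (increasing numeric vector, Hz), \code{step_octaves}
#'   and \code{f_min}.
#' @examples
#' pool <- build_frequency_pool()
#' length(pool$frequencies)  # 129
#' @export
build_frequency_pool <- function(f_min = 179, step_octaves = 1 / 24,
                                 f_max = 7246) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || !is.numeric(step_octaves) ||
      f_min <= 0 || step_octaves <= 0 || f_max < f_min) {
    stop("invalid pool parameters: need 0 < f_min <= f_max and step_octaves > 0")
  }
  k_max <- floor(log2(f_max / f_min) / step_octaves + 1e-12)
  freqs <- f_min * 2^((0:k_max) * step_octaves)
  structure(
    list(frequencies = freqs, step_octaves = step_octaves, f_min = f_min),
    class = "sfg_pool"
  )
}

#' @export
print.sfg_pool <- function(x, ...) {
  n <- length(x$frequencies)
  cat(sprintf(
    "<sfg_pool> %d frequencies, %.1f-%.1f Hz, step %.5f octaves\n",
    n, x$frequencies[1], x$frequencies[n], x$step_octaves
  ))
  invisible(x)
}
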