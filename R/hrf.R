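#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical two-gamma HRF (positive response peaking near 5 s
#' followed by a post-stimulus undershoot) on the interval \[0, 32\] s and
#' scales it to unit peak, so that event modulations carry the amplitude of
#' the convolved regressor.
#'
#' The impulse response is the difference of two gamma densities,
#' \deqn{h(t) = g(t; a_1, b) - g(t; a_2, b)/c,}
#' with peak delay `peak_delay` = \eqn{a_1 b} (default 6 s), undershoot
#' delay `undershoot_delay` = \eqn{a_2 b} (default 16 s), common dispersion
#' `dispersion` = \eqn{b} (default 1 s) and peak:undershoot ratio `ratio`
#' (default 6).
#'
#' @param dt sampling interval in seconds; must satisfy 0 < dt <= 2.
#' @param duration support of the sampled response in seconds (default 32).
#' @param peak_delay,undershoot_delay,dispersion,ratio shape parameters, see
#'   Details.
#'
#' @return numeric vector of length `duration/dt + 1`, max value 1.
#' @examples
#' h <- canonical_hrf(0.1)
#' (which.max(h) - 1) * 0.1 # time to peak, seconds
#' @export
canonical_hrf <- function(dt, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, dispersion = 1, ratio = 6) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0 || dt > 2)
    stop("'dt' must be a single value in (0, 2]", call. = FALSE)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    stats::dgamma(t, shape = undershoot_delay / dispersion,
                  scale = dispersion) / ratio
  h / max(h)
}
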