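#' Zero-lag low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward so the net
#' response has zero phase lag, the standard pre-processing for marker
#' trajectories. A net order `order` filter uses an `order/2` design per
#' pass, and the two passes leave the gain at the nominal cutoff at 0.5
#' (the squared single-pass -3 dB gain); no cutoff correction is applied.
#' Edge transients are controlled by odd (point-symmetric) reflection
#' padding, which preserves DC and linear trends at the boundaries.
#'
#' @param x numeric series.
#' @param sample_rate_hz sampling rate (Hz).
#' @param cutoff_hz low-pass cutoff (Hz); must be below the Nyquist rate.
#'   Default 10 Hz.
#' @param order net filter order after both passes; a positive even number.
#'   Default 4 (i.e. 2nd order per pass).
#' @return Filtered numeric series, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' noisy <- sin(2 * pi * t) + rnorm(length(t), 0, 0.05)
#' smooth <- lowpass_zero_lag(noisy, 100)
lowpass_zero_lag <- function(x, sample_rate_hz, cutoff_hz = 10, order = 4) {
  if (cutoff_hz >= sample_rate_hz / 2) {
    stop("lowpass_zero_lag: cutoff must be below the Nyquist frequency",
         call. = FALSE)
  }
  if (order < 2 || order %% 2 != 0) {
    stop("lowpass_zero_lag: order must be a positive even integer", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("lowpass_zero_lag: series too short", call. = FALSE)
  bf <- signal::butter(order / 2, cutoff_hz / (sample_rate_hz / 2), type = "low")
  # >= 3 filter lengths of padding; bounded by the series length
  p <- min(n - 1, max(ceiling(3 * sample_rate_hz / cutoff_hz), 3 * (order + 1)))
  left <- 2 * x[1] - x[seq(p + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - p)]
  xp <- c(left, x, right)
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(p + 1):(p + n)]
}

#' Numerical differentiation by central differences
#'
#' First or second time derivative of a uniformly sampled series: central
#' differences in the interior (exact for quadratics), one-sided differences
#' at the endpoints. The second derivative applies the operator twice.
#'
#' @param x numeric series, length >= 3.
#' @param sample_rate_hz sampling rate (Hz).
#' @param n derivative order, 1 or 2.
#' @return Numeric series of the same length; units scale by
#'   `sample_rate_hz` per application.
#' @export
derivative <- function(x, sample_rate_hz, n = 1) {
  if (length(x) < 3) {
    stop("derivative: series must have at least 3 samples", call. = FALSE)
  }
  if (!n %in% c(1, 2)) {
    stop("derivative: n must be 1 or 2", call. = FALSE)
  }
  d1 <- function(v) {
    m <- length(v)
    out <- numeric(m)
    out[2:(m - 1)] <- (v[3:m] - v[1:(m - 2)]) * sample_rate_hz / 2
    out[1] <- (v[2] - v[1]) * sample_rate_hz
    out[m] <- (v[m] - v[m - 1]) * sample_rate_hz
    out
  }
  y <- d1(x)
  if (n == 2) y <- d1(y)
  y
}
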