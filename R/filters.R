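#' Design a digital Butterworth low-pass filter
#'
#' Thin wrapper around [signal::butter()] that validates the cutoff
#' against the Nyquist frequency and returns the transfer-function
#' coefficients.
#'
#' @param order filter order (the package uses 4 throughout).
#' @param cutoff_hz cutoff frequency in Hz; must be below `rate_hz / 2`.
#' @param rate_hz sampling rate in Hz.
#' @return a list with numerator `b` and denominator `a` coefficients.
#' @export
butter_lowpass <- function(order, cutoff_hz, rate_hz) {
  nyq <- rate_hz / 2
  if (cutoff_hz >= nyq)
    stop(sprintf(
      "butter_lowpass: cutoff %g Hz must be below the Nyquist frequency %g Hz",
      cutoff_hz, nyq), call. = FALSE)
  if (cutoff_hz <= 0) stop("butter_lowpass: cutoff must be positive",
                           call. = FALSE)
  flt <- signal::butter(order, cutoff_hz / nyq, type = "low")
  list(b = as.numeric(flt$b), a = as.numeric(flt$a),
       order = order, cutoff_hz = cutoff_hz, rate_hz = rate_hz)
}

# Zero-phase (forward-backward) application; squares the magnitude
# response and cancels phase, so no group delay biases event timing.
# The signal is extended by odd reflection at both ends before
# filtering so start-up transients die out inside the padding; the pad
# length covers the slowest pole's decay to ~1e-12.
zero_phase <- function(flt, x) {
  n <- length(x)
  padlen <- min(n - 1L, as.integer(round(12 * flt$rate_hz / flt$cutoff_hz)))
  if (padlen < 1L)
    return(as.numeric(signal::filtfilt(signal::Arma(b = flt$b, a = flt$a), x)))
  pre <- 2 * x[1] - x[(padlen + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  xt <- c(pre, x, post)
  yt <- as.numeric(signal::filtfilt(signal::Arma(b = flt$b, a = flt$a), xt))
  yt[(padlen + 1L):(padlen + n)]
}

#' Complex frequency response of a designed filter
#'
#' Evaluates H(e^{i 2 pi f / fs}) = B(z)/A(z) directly from the
#' coefficients. Used to verify the implemented filters against the
#' analytic Butterworth magnitude response.
#'
#' @param flt a filter from [butter_lowpass()].
#' @param freq_hz frequencies at which to evaluate, in Hz.
#' @return complex vector of responses, one per frequency.
#' @export
filter_response <- function(flt, freq_hz) {
  w <- 2 * pi * freq_hz / flt$rate_hz
  vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(flt$b) - 1))
    num <- sum(flt$b * z)
    zden <- exp(-1i * wi * (seq_along(flt$a) - 1))
    num / sum(flt$a * zden)
  }, complex(1))
}
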