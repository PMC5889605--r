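#' Uniformly sampled time series
#'
#' Lightweight container for a single real-valued channel sampled at a
#' constant rate. All signals in the package (marker trajectories, raw
#' sEMG, envelopes) travel as `emg_ts` objects.
#'
#' @param values numeric vector of samples; must be finite and of length
#'   at least 2.
#' @param rate_hz sampling rate in Hz, > 0.
#' @param label channel name, e.g. `"hoofL_z"` or `"L_GM2"`.
#' @param start_time_s time of the first sample in seconds.
#' @return an object of class `emg_ts` with fields `values`, `rate_hz`,
#'   `label`, `start_time_s`.
#' @export
time_series <- function(values, rate_hz, label = "", start_time_s = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("time_series: 'values' must have length >= 2", call. = FALSE)
  if (!all(is.finite(values)))
    stop("time_series: 'values' must be finite", call. = FALSE)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("time_series: 'rate_hz' must be a single positive number",
         call. = FALSE)
  structure(
    list(values = values, rate_hz = as.numeric(rate_hz),
         label = as.character(label), start_time_s = as.numeric(start_time_s)),
    class = "emg_ts")
}

#' @export
print.emg_ts <- function(x, ...) {
  cat(sprintf("<emg_ts '%s': %d samples @ %g Hz, t0 = %g s>\n",
              x$label, length(x$values), x$rate_hz, x$start_time_s))
  invisible(x)
}

#' @export
length.emg_ts <- function(x) length(x$values)

#' Sample times of a time series
#' @param ts an `emg_ts` object.
#' @return numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) {
  ts$start_time_s + (seq_along(ts$values) - 1) / ts$rate_hz
}

is_ts <- function(x) inherits(x, "emg_ts")

assert_ts <- function(x, arg = deparse(substitute(x))) {
  if (!is_ts(x))
    stop(sprintf("'%s' must be an emg_ts object (see time_series())", arg),
         call. = FALSE)
  invisible(x)
}
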