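#' @title Surface EMG conditioning chain
#' @description
#' The raw sEMG conditioning chain, applied in this fixed order:
#' DC-offset removal, full-wave rectification, decimation to 120 Hz,
#' zero-phase fourth-order 20 Hz Butterworth low-pass, and per-electrode
#' per-data-collection-day maximum normalization. No high-pass filter is
#' part of the chain. [preprocess_emg()] runs the per-channel steps;
#' [normalize_session()] applies the session-level scaling.
#' @name emg-preprocess
NULL

#' Remove the DC offset
#'
#' Subtracts the channel mean so the signal is zero-mean before
#' rectification.
#'
#' @param ts an [time_series()].
#' @return the zero-mean trace, same length and rate.
#' @export
remove_dc <- function(ts) {
  assert_ts(ts)
  ts$values <- ts$values - mean(ts$values)
  ts
}

#' Full-wave rectification
#'
#' Elementwise absolute value; idempotent.
#'
#' @param ts an [time_series()].
#' @return the rectified trace.
#' @export
rectify <- function(ts) {
  assert_ts(ts)
  ts$values <- abs(ts$values)
  ts
}

#' Reduce the sampling rate to the kinematic rate
#'
#' Decimates the (rectified) sEMG to `target_hz`. For an integer rate
#' ratio a zero-phase fourth-order Butterworth anti-aliasing low-pass at
#' `0.4 x target_hz` (48 Hz for the default 120 Hz) precedes index
#' selection; for a non-integer ratio the anti-aliased trace is linearly
#' interpolated onto the target grid. A trace already at the target rate
#' is returned unchanged.
#'
#' @param ts an [time_series()] with `rate_hz >= target_hz`.
#' @param target_hz output rate (the study uses 120 Hz).
#' @return the decimated trace at `target_hz`.
#' @export
downsample <- function(ts, target_hz = 120) {
  assert_ts(ts)
  if (ts$rate_hz < target_hz)
    stop(sprintf("downsample: input rate %g Hz is below target %g Hz",
                 ts$rate_hz, target_hz), call. = FALSE)
  if (isTRUE(all.equal(ts$rate_hz, target_hz))) return(ts)
  flt <- butter_lowpass(4, 0.4 * target_hz, ts$rate_hz)
  smooth <- zero_phase(flt, ts$values)
  ratio <- ts$rate_hz / target_hz
  if (isTRUE(all.equal(ratio, round(ratio)))) {
    idx <- seq(1L, length(smooth), by = as.integer(round(ratio)))
    out_vals <- smooth[idx]
  } else {
    t_in <- ts_times(ts)
    t_out <- seq(ts$start_time_s, max(t_in), by = 1 / target_hz)
    out_vals <- stats::approx(t_in, smooth, xout = t_out)$y
  }
  out <- time_series(out_vals, target_hz, label = ts$label,
                     start_time_s = ts$start_time_s)
  out
}

#' Envelope low-pass
#'
#' Zero-phase fourth-order Butterworth low-pass at 20 Hz applied to the
#' rectified, decimated signal; the smoothing that turns rectified sEMG
#' into a linear envelope. Small negative filter outputs are clipped to
#' zero, honouring the rectified-signal contract.
#'
#' @param ts an [time_series()] at 120 Hz.
#' @param cutoff_hz cutoff in Hz (default 20).
#' @param order filter order (default 4).
#' @return the non-negative envelope, same length and rate.
#' @export
lowpass_envelope <- function(ts, cutoff_hz = 20, order = 4) {
  assert_ts(ts)
  if (!isTRUE(all.equal(ts$rate_hz, 120)))
    stop(sprintf(
      "lowpass_envelope: expected a 120 Hz trace, got %g Hz", ts$rate_hz),
      call. = FALSE)
  flt <- butter_lowpass(order, cutoff_hz, ts$rate_hz)
  ts$values <- pmax(zero_phase(flt, ts$values), 0)
  ts
}

#' Per-channel conditioning chain
#'
#' Runs DC removal, full-wave rectification, decimation to `target_hz`,
#' and the 20 Hz envelope low-pass, in that fixed order. Normalization is
#' a session-level step: see [normalize_session()].
#'
#' @param ts raw sEMG [time_series()].
#' @param target_hz output rate (default 120).
#' @param cutoff_hz envelope cutoff (default 20).
#' @return unnormalized envelope at `target_hz`.
#' @export
preprocess_emg <- function(ts, target_hz = 120, cutoff_hz = 20) {
  lowpass_envelope(downsample(rectify(remove_dc(ts)), target_hz),
                   cutoff_hz = cutoff_hz)
}

#' Normalize a set of envelopes to their pooled maximum
#'
#' Scales every envelope of one electrode position on one
#' data-collection day by the single maximum pooled over all its trials
#' (and, by default, both gaits), so the value 1 occurs at least once per
#' electrode per day.
#'
#' @param envelopes list of envelope [time_series()]s belonging to one
#'   (side, electrode position, DCD) group.
#' @return the same list, scaled; attribute `"norm_constant"` carries the
#'   pooled maximum and `"trial_of_max"` the list index attaining it.
#' @export
normalize_session <- function(envelopes) {
  if (!length(envelopes))
    stop("normalize_session: empty envelope list", call. = FALSE)
  lapply(envelopes, assert_ts)
  maxes <- vapply(envelopes, function(e) max(e$values), numeric(1))
  m <- max(maxes)
  if (m <= 0)
    stop(errorCondition(
      "normalize_session: pooled maximum is zero (degenerate channel)",
      class = c("degenerate_channel_error", "error")))
  out <- lapply(envelopes, function(e) {
    e$values <- e$values / m
    attr(e, "normalized") <- TRUE
    e
  })
  attr(out, "norm_constant") <- m
  attr(out, "trial_of_max") <- which.max(maxes)
  out
}
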