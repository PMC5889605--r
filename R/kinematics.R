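#' Motion cycle of one hind limb
#'
#' One stride delimited hoof-on to next hoof-on, as 1-based half-open
#' sample intervals. Stance is `[start_idx, hoof_off_idx)`, swing is
#' `[hoof_off_idx, end_idx)`; the two partition the cycle exactly.
#'
#' @param start_idx first sample of the cycle (hoof-on).
#' @param end_idx one past the last sample (next hoof-on).
#' @param hoof_off_idx first swing sample.
#' @param side `"L"` or `"R"`.
#' @return a `motion_cycle` object.
#' @export
motion_cycle <- function(start_idx, end_idx, hoof_off_idx, side = "L") {
  start_idx <- as.integer(start_idx); end_idx <- as.integer(end_idx)
  hoof_off_idx <- as.integer(hoof_off_idx)
  if (end_idx <= start_idx)
    stop("motion_cycle: 'end_idx' must exceed 'start_idx'", call. = FALSE)
  if (hoof_off_idx <= start_idx || hoof_off_idx > end_idx)
    stop("motion_cycle: 'hoof_off_idx' must lie inside (start_idx, end_idx]",
         call. = FALSE)
  if (!side %in% c("L", "R"))
    stop("motion_cycle: 'side' must be 'L' or 'R'", call. = FALSE)
  structure(list(start_idx = start_idx, end_idx = end_idx,
                 hoof_off_idx = hoof_off_idx, side = side),
            class = "motion_cycle")
}

#' Duty factor of a motion cycle
#' @param cycle a [motion_cycle()].
#' @return stance duration as a fraction of cycle duration.
#' @export
cycle_duty_factor <- function(cycle) {
  (cycle$hoof_off_idx - cycle$start_idx) / (cycle$end_idx - cycle$start_idx)
}

#' Low-pass filter marker kinematics
#'
#' Zero-phase Butterworth low-pass (order 4, cutoff 10 Hz by default)
#' applied to a kinematic trace before event detection, so skin-marker
#' noise does not produce spurious hoof-on events and no phase lag shifts
#' the detected events.
#'
#' @param ts an [time_series()]; `rate_hz` must exceed twice the cutoff.
#' @param cutoff_hz low-pass cutoff in Hz (default 10).
#' @param order filter order (default 4).
#' @return the filtered trace, same length and rate.
#' @export
lowpass_kinematics <- function(ts, cutoff_hz = 10, order = 4) {
  assert_ts(ts)
  flt <- butter_lowpass(order, cutoff_hz, ts$rate_hz)
  out <- ts
  out$values <- zero_phase(flt, ts$values)
  cyc <- attr(ts, "cycles")
  if (!is.null(cyc)) attr(out, "cycles") <- cyc
  out
}

#' Cut motion cycles from a vertical hoof trace
#'
#' Hoof-on is detected where the filtered vertical position falls below
#' `min + pos_frac x range` while the absolute vertical velocity is below
#' `vel_frac x` its peak; contiguous runs of that condition (after
#' hysteresis cleanup of sub-`gap_s` interruptions) are stance, and a
#' cycle spans hoof-on to the next hoof-on. Partial cycles at the trace
#' edges are discarded, except that a trailing segment whose length
#' matches the other cycles and that contains a full stance run is kept
#' as the final cycle.
#'
#' @param vertical_hoof filtered vertical hoof displacement
#'   ([lowpass_kinematics()] output).
#' @param min_cycles minimum acceptable number of cycles (6 at walk, 13
#'   at trot in the study protocol); fewer raises an
#'   `insufficient_cycles_error` carrying the count found.
#' @param side limb label attached to the cycles.
#' @param pos_frac position threshold as a fraction of the trace range.
#' @param vel_frac velocity threshold as a fraction of peak speed.
#' @param gap_s hysteresis: stance interruptions shorter than this are
#'   bridged; stance runs shorter than this are dropped.
#' @return list of [motion_cycle()]s.
#' @export
detect_cycles <- function(vertical_hoof, min_cycles = 1L, side = "L",
                          pos_frac = 0.10, vel_frac = 0.10, gap_s = 0.05) {
  assert_ts(vertical_hoof)
  v <- vertical_hoof$values
  n <- length(v)
  rate <- vertical_hoof$rate_hz
  rng <- max(v) - min(v)
  insufficient <- function(count) {
    stop(errorCondition(
      sprintf("detect_cycles: found %d cycles, need at least %d",
              count, min_cycles),
      count = count, class = c("insufficient_cycles_error", "error")))
  }
  if (rng <= .Machine$double.eps * max(abs(v), 1) * n) insufficient(0L)

  ev <- detect_events(vertical_hoof, pos_frac = pos_frac,
                      vel_frac = vel_frac, gap_s = gap_s)
  on_idx <- ev$on_idx; off_idx <- ev$off_idx

  if (length(on_idx) < 2L) {
    count <- max(0L, length(on_idx) - 1L)
    if (count < min_cycles) insufficient(count)
  }
  cycles <- list()
  for (i in seq_len(length(on_idx) - 1L)) {
    cycles[[i]] <- motion_cycle(on_idx[i], on_idx[i + 1L],
                                min(off_idx[i], on_idx[i + 1L]), side)
  }
  # trailing segment: accept as a final cycle if its length is ordinary
  if (length(on_idx) >= 2L) {
    gaps <- diff(on_idx)
    last_on <- on_idx[length(on_idx)]
    trail_len <- n + 1L - last_on
    med <- stats::median(gaps)
    if (trail_len >= 0.7 * med && trail_len <= 1.3 * med) {
      cycles[[length(cycles) + 1L]] <-
        motion_cycle(last_on, n + 1L,
                     min(off_idx[length(off_idx)], n + 1L), side)
    }
  }
  if (length(cycles) < min_cycles) insufficient(length(cycles))
  cycles
}

# Bridge FALSE gaps shorter than gap_n between TRUE runs, then drop TRUE
# runs shorter than gap_n (chatter suppression).
clean_mask <- function(mask, gap_n) {
  r <- rle(mask)
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    flip <- inner[!r$values[inner] & r$lengths[inner] < gap_n]
    r$values[flip] <- TRUE
  }
  mask <- inverse.rle(r)
  r <- rle(mask)
  r$values[r$values & r$lengths < gap_n] <- FALSE
  inverse.rle(r)
}

#' Phase map of a motion cycle
#'
#' Linear map from sample index to normalized cycle phase in \[0, 100):
#' the cycle start maps to 0 and the limit at the cycle end is 100.
#'
#' @param cycle a [motion_cycle()].
#' @return a `cycle_phase_map` object.
#' @export
cycle_phase_map <- function(cycle) {
  if (!inherits(cycle, "motion_cycle"))
    stop("cycle_phase_map: 'cycle' must be a motion_cycle", call. = FALSE)
  structure(list(cycle = cycle), class = "cycle_phase_map")
}

#' Normalized phase of a sample within a cycle
#'
#' @param map a [cycle_phase_map()].
#' @param idx sample index (may be fractional), with
#'   `start_idx <= idx < end_idx`.
#' @return phase in percent of the motion cycle, in \[0, 100).
#' @export
phase_of_sample <- function(map, idx) {
  cyc <- map$cycle
  if (any(idx < cyc$start_idx | idx >= cyc$end_idx))
    stop(errorCondition(
      "phase_of_sample: index outside the cycle",
      class = c("phase_range_error", "error")))
  100 * (idx - cyc$start_idx) / (cyc$end_idx - cyc$start_idx)
}

#' Sample index at a given cycle phase (inverse of [phase_of_sample()])
#' @param map a [cycle_phase_map()].
#' @param phase_pct phase in \[0, 100).
#' @return fractional sample index.
#' @export
index_of_phase <- function(map, phase_pct) {
  if (any(phase_pct < 0 | phase_pct >= 100))
    stop(errorCondition("index_of_phase: phase outside [0, 100)",
                        class = c("phase_range_error", "error")))
  cyc <- map$cycle
  cyc$start_idx + phase_pct / 100 * (cyc$end_idx - cyc$start_idx)
}

#' Detect right-limb cycles and pair them with left cycles
#'
#' Applies the same hoof-on rule to the right hoof trace and pairs each
#' right hoof-on event with the left cycle containing it, recording the
#' event's phase on the left-cycle axis. This is the phase reference that
#' lets left and right activity be compared within one common motion
#' cycle while stance/swing classification stays ipsilateral.
#'
#' @param left_cycles list of left [motion_cycle()]s.
#' @param right_hoof filtered right vertical hoof trace covering the same
#'   span as the left trace.
#' @param ... threshold arguments passed to the event detector (see
#'   [detect_cycles()]).
#' @return list of right-side [motion_cycle()]s with attribute
#'   `"pairing"`: a data frame of `right_start_idx`, `left_cycle`
#'   (index into `left_cycles`), and `hoofon_phase_pct` (right hoof-on on
#'   the left-cycle phase axis). Right events falling outside every left
#'   cycle are dropped with a warning.
#' @export
contralateral_cycles <- function(left_cycles, right_hoof, ...) {
  assert_ts(right_hoof)
  ev <- detect_events(right_hoof, ...)
  on_idx <- ev$on_idx; off_idx <- ev$off_idx
  if (length(on_idx) == 0L)
    stop(errorCondition("contralateral_cycles: no right hoof-on events found",
                        count = 0L,
                        class = c("insufficient_cycles_error", "error")))
  n <- length(right_hoof$values)
  gaps <- if (length(on_idx) > 1L) diff(on_idx) else integer()
  med <- if (length(gaps)) stats::median(gaps) else
    stats::median(vapply(left_cycles, function(c) c$end_idx - c$start_idx,
                         numeric(1)))
  lc_start <- vapply(left_cycles, `[[`, integer(1), "start_idx")
  lc_end <- vapply(left_cycles, `[[`, integer(1), "end_idx")

  out <- list(); pairing <- NULL
  for (i in seq_along(on_idx)) {
    e <- on_idx[i]
    j <- which(lc_start <= e & e < lc_end)
    if (length(j) != 1L) {
      warning(sprintf(
        "contralateral_cycles: right hoof-on at sample %d overlaps no left cycle; dropped", e))
      next
    }
    end_i <- if (i < length(on_idx)) on_idx[i + 1L] else
      min(n + 1L, e + as.integer(round(med)))
    off_i <- min(off_idx[i], end_i)
    out[[length(out) + 1L]] <- motion_cycle(e, end_i, off_i, side = "R")
    pairing <- rbind(pairing, data.frame(
      right_start_idx = e, left_cycle = j,
      hoofon_phase_pct = phase_of_sample(cycle_phase_map(left_cycles[[j]]), e)))
  }
  attr(out, "pairing") <- pairing
  out
}

# Shared event detector: stance-run starts (hoof-on) and run ends + 1
# (hoof-off), with the same thresholds and hysteresis as detect_cycles.
detect_events <- function(ts, pos_frac = 0.10, vel_frac = 0.10, gap_s = 0.05) {
  v <- ts$values; n <- length(v); rate <- ts$rate_hz
  rng <- max(v) - min(v)
  if (rng <= .Machine$double.eps * max(abs(v), 1) * n)
    return(list(on_idx = integer(), off_idx = integer()))
  vel <- c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) * rate
  pos_th <- min(v) + pos_frac * rng
  stance <- (v < pos_th) & (abs(vel) < vel_frac * max(abs(vel)))
  stance <- clean_mask(stance, max(1L, round(gap_s * rate)))
  r <- rle(stance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_idx <- starts[r$values]
  off_idx <- ends[r$values] + 1L
  # refine events to the position-only threshold crossing: the velocity
  # gate settles a few samples inside the plateau, so extend each run
  # outward while the filtered position stays below the threshold
  for (i in seq_along(on_idx)) {
    while (on_idx[i] > 1L && v[on_idx[i] - 1L] < pos_th)
      on_idx[i] <- on_idx[i] - 1L
    while (off_idx[i] <= n && v[off_idx[i]] < pos_th)
      off_idx[i] <- off_idx[i] + 1L
  }
  keep <- on_idx > 1L
  list(on_idx = on_idx[keep], off_idx = off_idx[keep])
}
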