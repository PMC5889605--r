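#' @title Synthetic gait and sEMG generation
#' @description Internal schedule machinery plus the exported generators.
#' @name synthetic-generate
NULL

# Draw the jittered cycle schedule for one trial. Consumes exactly
# `n_cycles` normal deviates, so kinematic and EMG generators seeded
# identically see the same schedule before drawing anything else.
# A short late-swing lead-in precedes the first hoof-on so that the first
# cycle boundary is an observable swing-to-stance transition.
draw_schedule <- function(spec) {
  z <- stats::rnorm(spec$n_cycles)
  dur <- spec$cycle_duration_s * pmax(0.25, 1 + spec$timing_jitter_cv * z)
  lead <- 0.15 * (1 - spec$duty_factor) * dur[1]
  starts <- lead + c(0, cumsum(dur))[seq_len(spec$n_cycles)]
  list(starts = starts, durations = dur, lead = lead,
       total = lead + sum(dur))
}

# Ground-truth cycle table (1-based sample indices, half-open [start, end)).
schedule_cycles <- function(sched, spec, rate, n_samp) {
  starts <- sched$starts
  dur <- sched$durations
  start_idx <- pmin(ceiling(starts * rate - 1e-9) + 1L, n_samp + 1L)
  end_idx <- c(start_idx[-1], n_samp + 1L)
  hoof_off <- pmin(ceiling((starts + spec$duty_factor * dur) * rate - 1e-9) + 1L,
                   end_idx)
  data.frame(cycle = seq_along(starts), start_idx = start_idx,
             end_idx = end_idx, hoof_off_idx = hoof_off,
             start_s = starts, duration_s = dur)
}

# Swing arc: half-sine raised to SWING_EXP. The sub-unity exponent gives
# steep lift-off and touch-down so the stance plateau stays crisply
# delimited while mid-swing remains a smooth arc.
SWING_EXP <- 0.5

swing_arc <- function(v) sin(pi * pmin(pmax(v, 0), 1))^SWING_EXP

#' Generate a synthetic vertical hoof-displacement trace
#'
#' Produces one trial of cyclic vertical hoof motion: a flat minimal
#' plateau during stance (duration `duty_factor` x cycle) and a smooth
#' positive arc during swing. Ground-truth cycle boundaries are attached
#' as the `"cycles"` attribute so segmentation can be scored without
#' circularity.
#'
#' @param spec a [gait_spec()].
#' @param rate sampling rate in Hz (kinematics use 120).
#' @param seed integer seed; the cycle schedule is drawn first so a
#'   matching [generate_emg_channel()] call with the same seed shares it.
#' @param side `"L"` or `"R"`; the right limb is offset by
#'   `spec$lr_phase_offset` of a cycle.
#' @param amplitude peak swing height (arbitrary length unit).
#' @param schedule optional precomputed schedule (internal; used by
#'   [generate_study()] to share one schedule across channels).
#' @return an [time_series()] with attribute `"cycles"`: a data frame of
#'   ground-truth `start_idx`, `end_idx`, `hoof_off_idx` (1-based,
#'   half-open) per complete cycle.
#' @export
generate_hoof_trajectory <- function(spec, rate = 120, seed = 1L,
                                     side = c("L", "R"), amplitude = 1,
                                     schedule = NULL) {
  if (!inherits(spec, "gait_spec"))
    stop("generate_hoof_trajectory: 'spec' must be a gait_spec", call. = FALSE)
  side <- match.arg(side)
  if (rate <= 0) stop("generate_hoof_trajectory: 'rate' must be > 0",
                      call. = FALSE)
  if (is.null(schedule))
    schedule <- with_seed(seed, draw_schedule(spec))
  n_samp <- floor(schedule$total * rate)
  t <- (seq_len(n_samp) - 1) / rate
  duty <- spec$duty_factor

  if (side == "L") {
    bnd <- c(schedule$starts, schedule$total)
  } else {
    startsR <- schedule$starts + spec$lr_phase_offset * schedule$durations
    # prepend a virtual cycle so early samples fall inside a right cycle
    bnd <- c(startsR[1] - schedule$durations[1], startsR,
             startsR[length(startsR)] +
               schedule$durations[length(schedule$durations)])
  }
  k <- findInterval(t, bnd, rightmost.closed = FALSE)
  k[k < 1L] <- 1L
  k[k >= length(bnd)] <- length(bnd) - 1L
  u <- (t - bnd[k]) / (bnd[k + 1] - bnd[k])
  u <- ifelse(u < 0, u + 1, u)   # lead-in samples are late swing (wrap)
  y <- ifelse(u < duty, 0, amplitude * swing_arc((u - duty) / (1 - duty)))

  ts <- time_series(y, rate, label = paste0("hoof", side, "_z"))
  if (side == "L") {
    attr(ts, "cycles") <- schedule_cycles(schedule, spec, rate, n_samp)
  } else {
    startsR <- schedule$starts + spec$lr_phase_offset * schedule$durations
    keep <- startsR + schedule$durations <= schedule$total + 1e-9
    schedR <- list(starts = startsR[keep], durations = schedule$durations[keep])
    if (any(keep))
      attr(ts, "cycles") <- schedule_cycles(schedR, spec, rate, n_samp)
  }
  attr(ts, "schedule") <- schedule
  ts
}

#' Generate a synthetic raw sEMG channel
#'
#' Zero-mean Gaussian broadband noise whose instantaneous standard
#' deviation is a constant noise floor plus Gaussian burst envelopes
#' placed at each burst's (per-cycle jittered) phase within every motion
#' cycle. The rectified-and-smoothed envelope therefore has local maxima
#' near the burst centers — the structure the downstream mixture model
#' assumes.
#'
#' Phases are referenced to the left-hind cycle schedule; callers place
#' right-side activity by shifting burst centers (see [generate_study()]).
#'
#' @param spec a [gait_spec()].
#' @param bursts non-empty list of [burst_spec()]s.
#' @param rate raw sampling rate in Hz, >= 240.
#' @param noise_floor baseline noise SD as a fraction of the largest
#'   burst amplitude.
#' @param seed integer seed (schedule drawn first; see
#'   [generate_hoof_trajectory()]).
#' @param schedule optional precomputed schedule.
#' @return an [time_series()] with attributes `"cycles"` (ground truth at
#'   `rate`) and `"burst_centers"` (nominal centers, % of cycle).
#' @export
generate_emg_channel <- function(spec, bursts, rate = 1200,
                                 noise_floor = 0.05, seed = 1L,
                                 schedule = NULL) {
  if (!inherits(spec, "gait_spec"))
    stop("generate_emg_channel: 'spec' must be a gait_spec", call. = FALSE)
  if (length(bursts) < 1L)
    stop("generate_emg_channel: 'bursts' must contain at least one burst_spec",
         call. = FALSE)
  if (!all(vapply(bursts, inherits, logical(1), "burst_spec")))
    stop("generate_emg_channel: all 'bursts' must be burst_spec objects",
         call. = FALSE)
  if (rate < 240)
    stop("generate_emg_channel: 'rate' must be >= 240 Hz", call. = FALSE)

  gen <- function() {
    sched <- if (is.null(schedule)) draw_schedule(spec) else schedule
    n_samp <- floor(sched$total * rate)
    t <- (seq_len(n_samp) - 1) / rate
    bnd <- c(sched$starts, sched$total)
    k <- findInterval(t, bnd)
    k[k < 1L] <- 1L
    k[k > spec$n_cycles] <- spec$n_cycles
    ph <- (100 * (t - bnd[k]) / (bnd[k + 1] - bnd[k])) %% 100

    amps <- vapply(bursts, `[[`, numeric(1), "rel_amplitude")
    sd_t <- rep(noise_floor * max(amps), n_samp)
    # per-cycle jittered centers, one matrix draw to keep the stream fixed
    jit <- matrix(stats::rnorm(spec$n_cycles * length(bursts)),
                  nrow = spec$n_cycles)
    for (b in seq_along(bursts)) {
      bs <- bursts[[b]]
      centers <- (bs$center_phase_pct +
                    bs$phase_jitter_sd_pct * jit[, b]) %% 100
      d <- abs(ph - centers[k])
      d <- pmin(d, 100 - d)
      sd_t <- sd_t + bs$rel_amplitude * exp(-0.5 * (d / bs$width_pct)^2)
    }
    stats::rnorm(n_samp) * sd_t
  }
  vals <- with_seed(seed, gen())
  # replay the schedule draw (same seed, same first deviates) for ground truth
  sched <- if (is.null(schedule)) with_seed(seed, draw_schedule(spec))
           else schedule
  ts <- time_series(vals, rate, label = "emg")
  attr(ts, "cycles") <- schedule_cycles(sched, spec, rate, length(vals))
  attr(ts, "burst_centers") <-
    vapply(bursts, `[[`, numeric(1), "center_phase_pct")
  attr(ts, "schedule") <- sched
  ts
}

#' Ground-truth motion cycles of a generated trace
#'
#' Converts the `"cycles"` attribute that the generators attach into a
#' list of [motion_cycle()]s, e.g. to score segmentation or to extract
#' peaks against known cycle boundaries.
#'
#' @param ts a trace from [generate_hoof_trajectory()] or
#'   [generate_emg_channel()].
#' @param side limb label for the cycles.
#' @return list of [motion_cycle()]s.
#' @export
ground_truth_cycles <- function(ts, side = "L") {
  gt <- attr(ts, "cycles")
  if (is.null(gt))
    stop("ground_truth_cycles: trace carries no ground-truth cycle table",
         call. = FALSE)
  n <- length(ts$values)
  out <- list()
  for (i in seq_len(nrow(gt))) {
    if (gt$end_idx[i] - 1L > n) next
    out[[length(out) + 1L]] <-
      motion_cycle(gt$start_idx[i], gt$end_idx[i], gt$hoof_off_idx[i], side)
  }
  out
}

#' Write a full synthetic study to disk
#'
#' Generates kinematics and raw-EMG CSV files for every
#' horse x DCD x gait x trial in the session layout, together with a JSON
#' manifest recording the seed, the specs, per-trial ground-truth cycle
#' boundaries and the burst phases of every channel. Re-running with the
#' same specs and seed reproduces byte-identical files.
#'
#' @param spec a [session_spec()].
#' @param gait_specs named list of [gait_spec()]s (subset of walk/trot).
#' @param burst_library named list (per electrode position) of lists of
#'   [burst_spec()]s, referenced to the ipsilateral limb; right-side
#'   channels are shifted by the gait's `lr_phase_offset`.
#' @param out_dir output directory, created if needed.
#' @param overwrite refuse to clobber an existing manifest unless `TRUE`.
#' @return (invisibly) the manifest as a list.
#' @export
generate_study <- function(spec, gait_specs = default_gait_specs(),
                           burst_library = default_burst_library(),
                           out_dir, overwrite = FALSE) {
  if (!inherits(spec, "session_spec"))
    stop("generate_study: 'spec' must be a session_spec", call. = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop(sprintf("generate_study: manifest already exists at %s (use overwrite = TRUE)",
                 manifest_path), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  missing_el <- setdiff(spec$electrodes, names(burst_library))
  if (length(missing_el))
    stop(sprintf("generate_study: burst_library lacks electrode(s): %s",
                 paste(missing_el, collapse = ", ")), call. = FALSE)

  combos <- expand.grid(trial = seq_len(spec$trials_per_gait),
                        gait = names(gait_specs), dcd = spec$dcds,
                        horse = spec$horses, stringsAsFactors = FALSE)
  # one seed per trial and per EMG channel, all derived from the master seed
  n_chan <- length(spec$sides) * length(spec$electrodes)
  seeds <- with_seed(spec$seed,
                     sample.int(.Machine$integer.max - 1,
                                nrow(combos) * (1 + n_chan)))
  trials <- vector("list", nrow(combos))

  for (i in seq_len(nrow(combos))) {
    row <- combos[i, ]
    gs <- gait_specs[[row$gait]]
    base <- (i - 1) * (1 + n_chan)
    trial_seed <- seeds[base + 1]
    sched <- with_seed(trial_seed, draw_schedule(gs))

    hoofL <- generate_hoof_trajectory(gs, spec$kin_rate_hz, side = "L",
                                      schedule = sched)
    hoofR <- generate_hoof_trajectory(gs, spec$kin_rate_hz, side = "R",
                                      schedule = sched)
    kin <- data.frame(time_s = ts_times(hoofL),
                      hoofL_z = hoofL$values, hoofR_z = hoofR$values)

    stem <- sprintf("%s_DCD%d_%s_T%d", row$horse, row$dcd, row$gait, row$trial)
    kin_file <- paste0(stem, "_kin.csv")
    utils::write.csv(kin, file.path(out_dir, kin_file), row.names = FALSE)

    emg <- data.frame(time_s = (seq_len(floor(sched$total * spec$emg_rate_hz)) - 1) /
                        spec$emg_rate_hz)
    chan_info <- list()
    ci <- 0L
    for (side in spec$sides) {
      for (el in spec$electrodes) {
        ci <- ci + 1L
        bursts <- burst_library[[el]]
        if (side == "R") {
          shift <- gs$lr_phase_offset * 100
          bursts <- lapply(bursts, function(b) {
            b$center_phase_pct <- (b$center_phase_pct + shift) %% 100
            b
          })
        }
        ch <- generate_emg_channel(gs, bursts, rate = spec$emg_rate_hz,
                                   noise_floor = spec$noise_floor,
                                   seed = seeds[base + 1 + ci],
                                   schedule = sched)
        nm <- paste(side, el, sep = "_")
        emg[[nm]] <- ch$values[seq_len(nrow(emg))]
        chan_info[[nm]] <- list(
          burst_phases = vapply(bursts, `[[`, numeric(1), "center_phase_pct"),
          over_scar = (el == "GM2" && row$dcd == 3L))
      }
    }
    emg_file <- paste0(stem, "_emg.csv")
    utils::write.csv(emg, file.path(out_dir, emg_file), row.names = FALSE)

    cyc <- attr(hoofL, "cycles")
    cycR <- attr(hoofR, "cycles")
    trials[[i]] <- list(
      horse = row$horse, dcd = row$dcd, gait = row$gait, trial = row$trial,
      kin_file = kin_file, emg_file = emg_file, seed = trial_seed,
      n_cycles = nrow(cyc),
      cycle_start_idx = cyc$start_idx, cycle_end_idx = cyc$end_idx,
      hoof_off_idx = cyc$hoof_off_idx,
      right_cycle_start_idx = if (!is.null(cycR)) cycR$start_idx else integer(),
      channels = chan_info)
  }

  manifest <- list(
    seed = spec$seed,
    session = unclass(spec),
    gait_specs = lapply(gait_specs, unclass),
    hoofon_convention = "cycles run hoof-on to next hoof-on",
    trials = trials)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
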