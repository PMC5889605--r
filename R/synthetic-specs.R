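#' Gait specification for the synthetic generator
#'
#' Describes one gait's cyclic structure: cycle duration, duty factor
#' (stance fraction), the phase offset of the right hind limb relative to
#' the left, the number of cycles per trial and the cycle-to-cycle timing
#' jitter. Defaults are typical treadmill values for equine walk and trot;
#' hind limbs alternate at half a cycle in both gaits.
#'
#' @param gait `"walk"` or `"trot"`.
#' @param cycle_duration_s mean motion-cycle duration in seconds, > 0.
#' @param duty_factor stance fraction of the cycle, strictly in (0, 1).
#'   Defaults: 0.62 at walk, 0.42 at trot.
#' @param lr_phase_offset right hind hoof-on relative to left, as a
#'   fraction of the cycle in \[0, 1). Default 0.5.
#' @param n_cycles number of motion cycles per trial, >= 1.
#' @param timing_jitter_cv coefficient of variation of the cycle
#'   duration, >= 0.
#' @return a validated `gait_spec` list.
#' @export
gait_spec <- function(gait = c("walk", "trot"),
                      cycle_duration_s = NULL,
                      duty_factor = NULL,
                      lr_phase_offset = 0.5,
                      n_cycles = NULL,
                      timing_jitter_cv = 0.02) {
  gait <- match.arg(gait)
  if (is.null(cycle_duration_s))
    cycle_duration_s <- if (gait == "walk") 1.1 else 0.7
  if (is.null(duty_factor))
    duty_factor <- if (gait == "walk") 0.62 else 0.42
  if (is.null(n_cycles))
    n_cycles <- if (gait == "walk") 6L else 13L
  if (!is.numeric(cycle_duration_s) || cycle_duration_s <= 0)
    stop("gait_spec: 'cycle_duration_s' must be > 0", call. = FALSE)
  if (!is.numeric(duty_factor) || duty_factor <= 0 || duty_factor >= 1)
    stop("gait_spec: 'duty_factor' must be strictly between 0 and 1",
         call. = FALSE)
  if (lr_phase_offset < 0 || lr_phase_offset >= 1)
    stop("gait_spec: 'lr_phase_offset' must be in [0, 1)", call. = FALSE)
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L)
    stop("gait_spec: 'n_cycles' must be a positive integer", call. = FALSE)
  if (timing_jitter_cv < 0)
    stop("gait_spec: 'timing_jitter_cv' must be >= 0", call. = FALSE)
  structure(list(gait = gait, cycle_duration_s = cycle_duration_s,
                 duty_factor = duty_factor, lr_phase_offset = lr_phase_offset,
                 n_cycles = n_cycles, timing_jitter_cv = timing_jitter_cv),
            class = "gait_spec")
}

#' Activity-burst specification
#'
#' One focus of muscle activity within the motion cycle, modelled as a
#' Gaussian envelope that amplitude-modulates broadband noise.
#'
#' @param center_phase_pct burst center as % of cycle in \[0, 100).
#' @param rel_amplitude burst amplitude relative to other bursts, > 0.
#' @param width_pct Gaussian SD of the burst envelope, in % of cycle, > 0.
#' @param phase_jitter_sd_pct per-cycle SD of the burst center, in % of
#'   cycle, >= 0.
#' @return a validated `burst_spec` list.
#' @export
burst_spec <- function(center_phase_pct, rel_amplitude = 1,
                       width_pct = 3, phase_jitter_sd_pct = 0.5) {
  if (center_phase_pct < 0 || center_phase_pct >= 100)
    stop("burst_spec: 'center_phase_pct' must be in [0, 100)", call. = FALSE)
  if (rel_amplitude <= 0)
    stop("burst_spec: 'rel_amplitude' must be > 0", call. = FALSE)
  if (width_pct <= 0)
    stop("burst_spec: 'width_pct' must be > 0", call. = FALSE)
  if (phase_jitter_sd_pct < 0)
    stop("burst_spec: 'phase_jitter_sd_pct' must be >= 0", call. = FALSE)
  structure(list(center_phase_pct = center_phase_pct,
                 rel_amplitude = rel_amplitude, width_pct = width_pct,
                 phase_jitter_sd_pct = phase_jitter_sd_pct),
            class = "burst_spec")
}

#' Session layout specification
#'
#' Describes a full study layout: horses, data-collection days (DCDs),
#' trials per gait, electrode grid, and sampling rates.
#'
#' @param horses character vector of horse ids.
#' @param dcds integer subset of `1:3`.
#' @param trials_per_gait trials recorded per gait per DCD (default 3).
#' @param electrodes electrode positions per side; subset of
#'   `c("GM1", "GM2", "GM3")`.
#' @param sides subset of `c("L", "R")`.
#' @param emg_rate_hz raw sEMG sampling rate; must be >= 240 Hz so that
#'   decimation to 120 Hz is well posed. Default 1200.
#' @param kin_rate_hz kinematic sampling rate; fixed at 120 Hz.
#' @param noise_floor baseline noise SD as a fraction of the largest
#'   burst amplitude.
#' @param seed integer master seed for the whole session.
#' @return a validated `session_spec` list.
#' @export
session_spec <- function(horses = "H01", dcds = 1L, trials_per_gait = 3L,
                         electrodes = c("GM1", "GM2", "GM3"),
                         sides = c("L", "R"),
                         emg_rate_hz = 1200, kin_rate_hz = 120,
                         noise_floor = 0.05, seed = 1L) {
  dcds <- as.integer(dcds)
  if (!all(dcds %in% 1:3)) stop("session_spec: 'dcds' must be a subset of 1:3",
                                call. = FALSE)
  if (!all(electrodes %in% c("GM1", "GM2", "GM3")))
    stop("session_spec: 'electrodes' must be within GM1/GM2/GM3",
         call. = FALSE)
  if (!all(sides %in% c("L", "R")))
    stop("session_spec: 'sides' must be within L/R", call. = FALSE)
  if (emg_rate_hz < 240)
    stop("session_spec: 'emg_rate_hz' must be >= 240 Hz", call. = FALSE)
  if (kin_rate_hz != 120)
    stop("session_spec: 'kin_rate_hz' is fixed at 120 Hz", call. = FALSE)
  trials_per_gait <- as.integer(trials_per_gait)
  if (trials_per_gait < 1L)
    stop("session_spec: 'trials_per_gait' must be >= 1", call. = FALSE)
  if (noise_floor < 0)
    stop("session_spec: 'noise_floor' must be >= 0", call. = FALSE)
  structure(list(horses = as.character(horses), dcds = dcds,
                 trials_per_gait = trials_per_gait,
                 electrodes = electrodes, sides = sides,
                 emg_rate_hz = emg_rate_hz, kin_rate_hz = kin_rate_hz,
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "session_spec")
}

#' Default gait specifications for walk and trot
#' @return named list with `walk` and `trot` [gait_spec()]s.
#' @export
default_gait_specs <- function() {
  list(walk = gait_spec("walk"), trot = gait_spec("trot"))
}

#' Default burst library for the three gluteus medius electrodes
#'
#' Two activity foci per electrode referenced to the ipsilateral limb:
#' a dominant burst just after hoof-on (early stance, hip extension
#' under load) and a smaller one in late swing (protraction braking),
#' with small per-position timing offsets so adjacent electrodes differ
#' subtly, as adjacent sites on one muscle do.
#'
#' @return named list `GM1`, `GM2`, `GM3`, each a list of [burst_spec()]s.
#' @export
default_burst_library <- function() {
  offs <- c(GM1 = -1.5, GM2 = 0, GM3 = 1.5)
  lapply(offs, function(o) {
    list(
      burst_spec(center_phase_pct = (10 + o) %% 100, rel_amplitude = 1,
                 width_pct = 4, phase_jitter_sd_pct = 0.8),
      burst_spec(center_phase_pct = (88 + o) %% 100, rel_amplitude = 0.6,
                 width_pct = 3.5, phase_jitter_sd_pct = 0.8))
  })
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
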