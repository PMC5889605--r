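# Independent oracles and shared fixtures for the test suite.

# Closed-form magnitude response of a digital Butterworth low-pass
# designed by bilinear transform with cutoff prewarping:
# |H(f)|^2 = 1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^(2n)).
butter_magnitude_analytic <- function(f, fc, fs, order) {
  ratio <- tan(pi * f / fs) / tan(pi * fc / fs)
  1 / sqrt(1 + ratio^(2 * order))
}

# Brute-force log-likelihood of a two-component Gaussian mixture over a
# parameter grid; returns the best grid point's log-likelihood.
gmm2_grid_loglik <- function(x, n_mu = 25, n_sd = 8, n_w = 9) {
  mus <- seq(min(x), max(x), length.out = n_mu)
  sds <- seq(max(stats::sd(x) / 10, 0.25), stats::sd(x) * 1.5,
             length.out = n_sd)
  ws <- seq(0.1, 0.9, length.out = n_w)
  best <- -Inf
  for (m1 in mus) for (m2 in mus) {
    if (m2 < m1) next
    for (s in sds) for (w in ws) {
      ll <- sum(log(w * stats::dnorm(x, m1, s) +
                      (1 - w) * stats::dnorm(x, m2, s)))
      if (ll > best) best <- ll
    }
  }
  best
}

# A pooled peak set from a channel carrying ten well-separated bursts,
# run through the real preprocessing chain against ground-truth cycles.
ten_burst_centers <- seq(5, 95, by = 10)

make_ten_burst_peaks <- function(seed, n_cycles = 20, width_pct = 1.5,
                                 jitter = 0.3) {
  gs <- gait_spec("walk", n_cycles = n_cycles, timing_jitter_cv = 0.02)
  bursts <- lapply(ten_burst_centers, function(cc)
    burst_spec(cc, rel_amplitude = 1, width_pct = width_pct,
               phase_jitter_sd_pct = jitter))
  ch <- generate_emg_channel(gs, bursts, rate = 1200, noise_floor = 0.03,
                             seed = seed)
  env <- preprocess_emg(ch)
  hoof <- generate_hoof_trajectory(gs, 120, seed = seed)
  cycles <- ground_truth_cycles(hoof)
  peaks <- list()
  for (i in seq_along(cycles)) {
    cyc <- cycles[[i]]
    if (cyc$end_idx - 1L > length(env$values)) next
    peaks[[length(peaks) + 1L]] <-
      extract_cycle_peaks(env, cyc, cycle_id = i)
  }
  pool_peaks(peaks)
}

# Synthetic session on disk for pipeline-level tests; returns the config.
demo_config <- function(root, horses = "H01", dcds = 1L, sides = c("L", "R"),
                        gait_specs = default_gait_specs(),
                        trials_per_gait = 3L, seed = 11L, ...) {
  pipeline_config(
    data_dir = file.path(root, "data"), out_dir = file.path(root, "out"),
    synthetic = list(
      session = session_spec(horses = horses, dcds = dcds,
                             trials_per_gait = trials_per_gait,
                             sides = sides, seed = seed),
      gait_specs = gait_specs),
    seed = seed, overwrite = TRUE, ...)
}
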