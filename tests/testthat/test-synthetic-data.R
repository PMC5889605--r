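test_that("spec constructors validate their fields", {
  expect_error(gait_spec("walk", duty_factor = 1), "duty_factor")
  expect_error(gait_spec("walk", duty_factor = 0), "duty_factor")
  expect_error(gait_spec("walk", n_cycles = 0), "n_cycles")
  expect_error(gait_spec("walk", lr_phase_offset = 1), "lr_phase_offset")
  expect_error(gait_spec("walk", timing_jitter_cv = -0.1), "timing_jitter_cv")
  expect_error(burst_spec(120), "center_phase_pct")
  expect_error(burst_spec(10, width_pct = 0), "width_pct")
  expect_error(session_spec(emg_rate_hz = 200), "emg_rate_hz")
  expect_error(session_spec(kin_rate_hz = 100), "kin_rate_hz")
})

test_that("hoof trajectory has the specified cycle structure", {
  spec <- gait_spec("walk", n_cycles = 6, timing_jitter_cv = 0)
  h <- generate_hoof_trajectory(spec, 120, seed = 1)
  gt <- attr(h, "cycles")
  expect_equal(nrow(gt), 6)
  expect_true(all(gt$end_idx > gt$start_idx))
  # stance plateau duration: duty_factor 0.6 of a 1 s cycle at 120 Hz
  spec1 <- gait_spec("walk", cycle_duration_s = 1.0, duty_factor = 0.6,
                     n_cycles = 1, timing_jitter_cv = 0)
  h1 <- generate_hoof_trajectory(spec1, 120, seed = 1)
  n_low <- sum(h1$values < 0.05 * max(h1$values))
  expect_gte(n_low, 71)
  expect_lte(n_low, 73)
})

test_that("right-limb trace is the left trace shifted by half a cycle", {
  # jitter-free trot, cycle duration chosen so half a cycle is a whole
  # number of samples
  spec <- gait_spec("trot", cycle_duration_s = 0.8, lr_phase_offset = 0.5,
                    n_cycles = 5, timing_jitter_cv = 0)
  hL <- generate_hoof_trajectory(spec, 120, seed = 3, side = "L")
  hR <- generate_hoof_trajectory(spec, 120, seed = 3, side = "R")
  shift <- 0.5 * 0.8 * 120
  # compare within the steady cyclic region (skip the lead-in and the
  # final half cycle)
  gt <- attr(hL, "cycles")
  i0 <- gt$start_idx[2]; i1 <- gt$end_idx[4]
  expect_equal(hR$values[(i0 - shift):(i1 - shift)], hL$values[i0:i1],
               tolerance = 1e-10)
  # ground-truth right events lag left by exactly half a cycle
  gtR <- attr(hR, "cycles")
  lag <- gtR$start_s[1:4] - gt$start_s[1:4]
  expect_equal(lag, rep(0.4, 4), tolerance = 1e-9)
})

test_that("raw EMG is zero-mean broadband noise with burst structure", {
  spec <- gait_spec("walk", n_cycles = 10, timing_jitter_cv = 0)
  ch <- generate_emg_channel(spec, list(burst_spec(25, 1, 6, 0)),
                             rate = 1200, noise_floor = 0, seed = 4)
  se <- stats::sd(ch$values) / sqrt(length(ch$values))
  expect_lt(abs(mean(ch$values)), 3 * se)
  expect_error(generate_emg_channel(spec, list(), rate = 1200, seed = 1),
               "at least one burst")
  expect_error(generate_emg_channel(spec, list(burst_spec(25)), rate = 200,
                                    seed = 1), ">= 240")
})

test_that("preprocessed envelope peaks near the burst centers", {
  spec <- gait_spec("walk", n_cycles = 20, timing_jitter_cv = 0)
  ch <- generate_emg_channel(spec, list(burst_spec(25, 1, 6, 0)),
                             rate = 1200, noise_floor = 0, seed = 4)
  env <- preprocess_emg(ch)
  hoof <- generate_hoof_trajectory(spec, 120, seed = 4)
  gt <- attr(hoof, "cycles")
  imax <- which.max(env$values)
  k <- findInterval(imax, gt$start_idx)
  ph <- 100 * (imax - gt$start_idx[k]) / (gt$end_idx[k] - gt$start_idx[k])
  expect_gte(ph, 23); expect_lte(ph, 27)
})

test_that("ten bursts produce at least ten envelope maxima per cycle", {
  spec <- gait_spec("walk", n_cycles = 6, timing_jitter_cv = 0)
  bursts <- lapply(seq(5, 95, by = 10), function(cc)
    burst_spec(cc, 1, width_pct = 2, phase_jitter_sd_pct = 0))
  ch <- generate_emg_channel(spec, bursts, rate = 1200, noise_floor = 0.02,
                             seed = 6)
  env <- preprocess_emg(ch)
  hoof <- generate_hoof_trajectory(spec, 120, seed = 6)
  for (cyc in ground_truth_cycles(hoof)) {
    if (cyc$end_idx - 1L > length(env$values)) next
    seg <- env$values[cyc$start_idx:(cyc$end_idx - 1)]
    n_max <- sum(diff(sign(diff(seg))) < 0)
    expect_gte(n_max, 10)
  }
})

test_that("burst envelope fidelity: each burst center sits near an envelope maximum", {
  spec <- gait_spec("walk", n_cycles = 12, timing_jitter_cv = 0)
  centers <- c(15, 45, 80)
  bursts <- lapply(centers, function(cc) burst_spec(cc, 1, 3, 0))
  ch <- generate_emg_channel(spec, bursts, rate = 1200, noise_floor = 0,
                             seed = 7)
  env <- preprocess_emg(ch)
  hoof <- generate_hoof_trajectory(spec, 120, seed = 7)
  cycles <- ground_truth_cycles(hoof)
  # locate envelope maxima phases pooled over cycles
  phases <- c()
  for (i in seq_along(cycles)) {
    cyc <- cycles[[i]]
    if (cyc$end_idx - 1L > length(env$values)) next
    pk <- extract_cycle_peaks(env, cyc, n_peaks = 10, cycle_id = i)
    phases <- c(phases, pk$phase_pct)
  }
  for (cc in centers) {
    d <- abs(phases - cc); d <- pmin(d, 100 - d)
    expect_lt(stats::median(sort(d)[seq_len(10)]), 2)
  }
})

test_that("generate_study writes a deterministic dataset with correct cycle counts", {
  root <- withr::local_tempdir()
  sess <- session_spec(horses = "H01", dcds = 1L, trials_per_gait = 3L,
                       sides = "L", electrodes = "GM2", seed = 42L)
  gaits <- default_gait_specs()
  m1 <- generate_study(sess, gaits, out_dir = file.path(root, "a"))
  walk_cycles <- sum(vapply(m1$trials, function(tr)
    if (tr$gait == "walk") tr$n_cycles else 0L, numeric(1)))
  trot_cycles <- sum(vapply(m1$trials, function(tr)
    if (tr$gait == "trot") tr$n_cycles else 0L, numeric(1)))
  expect_equal(walk_cycles, 18)   # 3 trials x 6 cycles
  expect_equal(trot_cycles, 39)   # 3 trials x 13 cycles

  # byte-identical re-run under the same seed
  m2 <- generate_study(sess, gaits, out_dir = file.path(root, "b"))
  fa <- list.files(file.path(root, "a"), full.names = TRUE)
  fb <- list.files(file.path(root, "b"), full.names = TRUE)
  expect_equal(basename(fa), basename(fb))
  expect_equal(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))

  # refuses to clobber an existing manifest
  expect_error(generate_study(sess, gaits, out_dir = file.path(root, "a")),
               "overwrite")
  expect_silent(suppressMessages(
    generate_study(sess, gaits, out_dir = file.path(root, "a"),
                   overwrite = TRUE)))
})
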