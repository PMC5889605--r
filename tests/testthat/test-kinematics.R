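test_that("kinematic low-pass matches the analytic Butterworth response", {
  # constant trace passes unchanged (DC gain 1)
  const <- time_series(rep(2.5, 400), 120)
  expect_equal(lowpass_kinematics(const)$values, rep(2.5, 400),
               tolerance = 1e-9)

  # measured attenuation of pure tones vs the closed-form magnitude
  # (applied twice: zero-phase filtering squares the magnitude response)
  probe <- function(f_hz) {
    t <- (0:2399) / 120
    x <- time_series(sin(2 * pi * f_hz * t), 120)
    y <- lowpass_kinematics(x)$values
    core <- 600:1800  # avoid edge transients
    sqrt(mean(y[core]^2) / mean(x$values[core]^2))
  }
  expect_lt(abs(probe(2) - butter_magnitude_analytic(2, 10, 120, 4)^2), 0.01)
  expect_gt(butter_magnitude_analytic(2, 10, 120, 4)^2, 0.99)
  expect_lt(probe(30), 0.01)  # > 99% attenuation at 30 Hz

  # phase shift below one sample at 2 Hz: cross-correlation peak at lag 0
  t <- (0:1199) / 120
  x <- sin(2 * pi * 2 * t)
  y <- lowpass_kinematics(time_series(x, 120))$values
  lags <- -3:3
  cc <- vapply(lags, function(l)
    stats::cor(x[300:900], y[300:900 + l]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)

  expect_error(lowpass_kinematics(time_series(rnorm(100), 15)), "Nyquist")
})

test_that("cycle detection recovers ground truth within 2 samples", {
  for (g in c("walk", "trot")) {
    spec <- gait_spec(g, timing_jitter_cv = 0)
    h <- generate_hoof_trajectory(spec, 120, seed = 2)
    f <- lowpass_kinematics(h)
    cycles <- detect_cycles(f, min_cycles = spec$n_cycles)
    gt <- attr(h, "cycles")
    expect_length(cycles, nrow(gt))
    starts <- vapply(cycles, `[[`, integer(1), "start_idx")
    offs <- vapply(cycles, `[[`, integer(1), "hoof_off_idx")
    expect_lte(max(abs(starts - gt$start_idx)), 2)
    expect_lte(max(abs(offs - gt$hoof_off_idx)), 2)
  }
})

test_that("a flat standing trace raises an insufficient-cycles error with count 0", {
  flat <- time_series(rep(0.1, 600), 120)
  err <- tryCatch(detect_cycles(flat, min_cycles = 6), error = function(e) e)
  expect_s3_class(err, "insufficient_cycles_error")
  expect_equal(err$count, 0L)
})

test_that("the minimum-cycle rule is enforced with the count found", {
  spec <- gait_spec("walk", n_cycles = 4, timing_jitter_cv = 0)
  h <- lowpass_kinematics(generate_hoof_trajectory(spec, 120, seed = 5))
  err <- tryCatch(detect_cycles(h, min_cycles = 6), error = function(e) e)
  expect_s3_class(err, "insufficient_cycles_error")
  expect_lt(err$count, 6)
  expect_silent(detect_cycles(h, min_cycles = err$count))
})

test_that("phase mapping is the stated linear map and is invertible", {
  cyc <- motion_cycle(11, 107, 70)       # 96-sample cycle
  map <- cycle_phase_map(cyc)
  expect_equal(phase_of_sample(map, 11), 0)
  expect_equal(phase_of_sample(map, 11 + 48), 50)
  expect_equal(phase_of_sample(map, 11 + 24), 25)  # 100 x 24 / 96
  expect_error(phase_of_sample(map, 107), class = "phase_range_error")
  expect_error(phase_of_sample(map, 10), class = "phase_range_error")
  # strictly monotone, and inverse recovers the index
  idx <- 11:106
  ph <- phase_of_sample(map, idx)
  expect_true(all(diff(ph) > 0))
  expect_true(all(ph >= 0 & ph < 100))
  expect_equal(index_of_phase(map, ph), idx, tolerance = 1e-9)
  # 120-sample cycle midpoint
  map2 <- cycle_phase_map(motion_cycle(1, 121, 75))
  expect_equal(phase_of_sample(map2, 61), 50)
})

test_that("stance and swing partition every detected cycle exactly", {
  spec <- gait_spec("trot", timing_jitter_cv = 0.03)
  h <- lowpass_kinematics(generate_hoof_trajectory(spec, 120, seed = 8))
  for (cyc in detect_cycles(h, min_cycles = 10)) {
    stance_len <- cyc$hoof_off_idx - cyc$start_idx
    swing_len <- cyc$end_idx - cyc$hoof_off_idx
    expect_equal(stance_len + swing_len, cyc$end_idx - cyc$start_idx)
    expect_gt(stance_len, 0)
  }
})

test_that("segmentation and duty factor are recovered across random seeds", {
  for (seed in 1:8) {
    g <- if (seed %% 2 == 0) "walk" else "trot"
    spec <- gait_spec(g, timing_jitter_cv = 0.02)
    h <- generate_hoof_trajectory(spec, 120, seed = seed)
    f <- lowpass_kinematics(h)
    cycles <- detect_cycles(f, min_cycles = 1)
    expect_length(cycles, nrow(attr(h, "cycles")))
    duty <- mean(vapply(cycles, cycle_duty_factor, numeric(1)))
    expect_lt(abs(duty - spec$duty_factor), 0.05)
  }
})

test_that("contralateral pairing places right hoof-on at the generating offset", {
  spec <- gait_spec("trot", lr_phase_offset = 0.5, n_cycles = 6,
                    timing_jitter_cv = 0)
  hL <- lowpass_kinematics(generate_hoof_trajectory(spec, 120, seed = 3,
                                                    side = "L"))
  hR <- lowpass_kinematics(generate_hoof_trajectory(spec, 120, seed = 3,
                                                    side = "R"))
  left <- detect_cycles(hL, min_cycles = 6)
  right <- contralateral_cycles(left, hR)
  pairing <- attr(right, "pairing")
  expect_equal(nrow(pairing), 6)   # one right event per covered left cycle
  expect_true(all(abs(pairing$hoofon_phase_pct - 50) < 2))

  # degenerate symmetry: right trace identical to left pairs at phase 0
  right0 <- contralateral_cycles(left, hL)
  p0 <- attr(right0, "pairing")$hoofon_phase_pct
  expect_true(all(pmin(p0, 100 - p0) < 2))
})
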