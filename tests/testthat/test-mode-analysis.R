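make_env <- function(values) time_series(values, 120)

test_that("peak extraction keeps the highest interior maxima with the tie rule", {
  env <- make_env(c(0, 1, 0, 2, 0, 3, 0, 2, 0, 1, 0, 0))
  cyc <- motion_cycle(1, 13, 8)
  pk <- extract_cycle_peaks(env, cyc, n_peaks = 3)
  expect_equal(sort(pk$amplitude, decreasing = TRUE), c(3, 2, 2))
  # equal amplitudes break toward the earlier phase: both 2s beat the 1s
  expect_setequal(round(pk$phase_pct[pk$amplitude == 2]),
                  round(100 * c(3, 7) / 12))

  # 15 maxima, only ten survive
  vals <- rep(0, 31)
  vals[seq(2, 30, by = 2)] <- c(seq(1, 8), seq(7, 1))
  env15 <- make_env(vals)
  pk15 <- extract_cycle_peaks(env15, motion_cycle(1, 32, 16), n_peaks = 10)
  expect_equal(nrow(pk15), 10)
  expect_equal(min(pk15$amplitude), 3)  # the five smallest maxima dropped

  # strictly monotone envelope has no interior maximum
  mono <- make_env(seq(0, 1, length.out = 20))
  expect_warning(pk0 <- extract_cycle_peaks(mono, motion_cycle(1, 21, 11)),
                 "no interior")
  expect_equal(nrow(pk0), 0)

  # a plateau contributes its first sample
  plat <- make_env(c(0, 1, 2, 2, 2, 1, 0, 0))
  pkp <- extract_cycle_peaks(plat, motion_cycle(1, 9, 5))
  expect_equal(nrow(pkp), 1)
  expect_equal(pkp$phase_pct, 100 * 2 / 8)
})

test_that("peak pooling concatenates with provenance and enforces the cap", {
  one_cycle <- function(id, n) data.frame(
    phase_pct = seq(5, 95, length.out = n), amplitude = runif(n),
    cycle_id = id, side = "L")
  set.seed(1)
  pools <- lapply(1:18, one_cycle, n = 10)
  ps <- pool_peaks(pools)
  expect_equal(nrow(ps), 180)
  expect_true(all(table(ps$cycle_id) <= 10))

  expect_equal(nrow(pool_peaks(list())), 0)
  mix <- pool_peaks(list(one_cycle(1, 9), one_cycle(2, 10)))
  expect_equal(nrow(mix), 19)
  expect_error(pool_peaks(list(one_cycle(1, 11))), "more than 10")
  bad <- one_cycle(3, 5); bad$side <- "R"
  expect_error(pool_peaks(list(one_cycle(1, 5), bad)), "side")
})

test_that("the mixture fit recovers two tight clusters", {
  set.seed(20)
  x <- c(rnorm(100, 20, 1.5), rnorm(100, 70, 1.5))
  peaks <- data.frame(phase_pct = x, amplitude = runif(200, 0.4, 1),
                      cycle_id = rep(1:20, each = 10))
  fit <- fit_mixture(peaks, K_max = 10, seed = 1)
  expect_equal(fit$K, 2)
  expect_lt(abs(fit$means[1] - 20), 2)
  expect_lt(abs(fit$means[2] - 70), 2)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_true(all(fit$sds > 0))
  expect_true(all(fit$mode_values <= 1))

  # the EM log-likelihood beats a brute-force two-component grid
  small <- peaks[sample.int(200, 30), ]
  fit2 <- fit_mixture(small, K_max = 2, seed = 2)
  expect_gte(fit2$loglik, gmm2_grid_loglik(small$phase_pct) - 1e-6)
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  set.seed(11)
  x <- c(rnorm(80, 25, 2), rnorm(120, 72, 3))
  peaks <- data.frame(phase_pct = x, amplitude = runif(200),
                      cycle_id = rep(1:20, each = 10))
  fit <- fit_mixture(peaks, K_max = 2, seed = 4)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("degenerate and deterministic mixture behavior", {
  # all peaks at one phase collapse to a single mode there
  pk1 <- data.frame(phase_pct = rep(33, 25), amplitude = rep(0.8, 25),
                    cycle_id = rep(1:5, each = 5))
  fit1 <- fit_mixture(pk1, K_max = 10, seed = 3)
  expect_equal(fit1$K, 1)
  expect_equal(fit1$means, 33)
  expect_equal(fit1$mode_values, 0.8)

  expect_error(fit_mixture(data.frame(phase_pct = numeric(),
                                      amplitude = numeric(),
                                      cycle_id = integer())), "empty")

  # seed determinism
  set.seed(5)
  x <- c(rnorm(60, 30, 3), rnorm(60, 75, 3))
  pk <- data.frame(phase_pct = x, amplitude = runif(120),
                   cycle_id = rep(1:12, each = 10))
  fa <- fit_mixture(pk, seed = 7)
  fb <- fit_mixture(pk, seed = 7)
  expect_identical(fa$means, fb$means)
  expect_identical(fa$weights, fb$weights)

  # log-likelihood is non-decreasing along EM iterations
  expect_true(all(diff(fa$loglik_trace) > -1e-6 * max(1, abs(fa$loglik))))
})

test_that("ten well-separated bursts yield ten surviving modes", {
  pool <- make_ten_burst_peaks(seed = 31)
  fit <- fit_mixture(pool, K_max = 10, seed = 131)
  expect_equal(fit$K, 10)
  expect_lt(max(abs(fit$means - ten_burst_centers)), 2)
})

test_that("mode recovery holds across seeds", {
  # property: well-separated synthetic clusters are recovered within 2%
  ok <- 0L
  for (seed in 1:6) {
    set.seed(seed)
    truth <- c(12, 40, 81)
    x <- c(rnorm(60, truth[1], 1), rnorm(60, truth[2], 1),
           rnorm(60, truth[3], 1))
    pk <- data.frame(phase_pct = x, amplitude = runif(180, 0.3, 1),
                     cycle_id = rep(1:18, each = 10))
    fit <- fit_mixture(pk, K_max = 10, seed = seed + 50)
    if (fit$K == 3 && max(abs(fit$means - truth)) < 2) ok <- ok + 1L
  }
  expect_gte(ok, 5L)
})

test_that("phase summaries follow the dominant-mode and mean-MMV rules", {
  fit <- structure(list(K = 2, weights = c(0.6, 0.4), means = c(20, 80),
                        sds = c(2, 2), mode_values = c(0.4, 0.3)),
                   class = "mixture_fit")
  ps <- summarize_by_phase(fit, c(0, 60), c(60, 0))
  expect_equal(ps$MML_St, 20); expect_equal(ps$MMV_St, 0.4)
  expect_equal(ps$MML_Sw, 80); expect_equal(ps$MMV_Sw, 0.3)

  # two stance modes: MMV averages, MML follows the larger MMV
  fit2 <- structure(list(K = 2, weights = c(0.5, 0.5), means = c(10, 30),
                         sds = c(2, 2), mode_values = c(0.2, 0.5)),
                    class = "mixture_fit")
  ps2 <- suppressMessages(summarize_by_phase(fit2, c(0, 60), c(60, 0)))
  expect_equal(ps2$MMV_St, 0.35)
  expect_equal(ps2$MML_St, 30)
  expect_true(is.na(ps2$MML_Sw))
  expect_true(is.na(ps2$MMV_Sw))

  # wrapping stance interval (contralateral referencing)
  fit3 <- structure(list(K = 2, weights = c(0.5, 0.5), means = c(75, 30),
                         sds = c(2, 2), mode_values = c(0.6, 0.2)),
                    class = "mixture_fit")
  ps3 <- summarize_by_phase(fit3, c(50, 10), c(10, 50))
  expect_equal(ps3$MML_St, 75)
  expect_equal(ps3$MML_Sw, 30)

  expect_error(summarize_by_phase(fit, c(0, 70), c(60, 0)), "partition")
})

test_that("left-right MML shift is the circular distance", {
  mk <- function(st, sw) list(MML_St = st, MML_Sw = sw)
  expect_equal(unname(left_right_shift(mk(25, 76), mk(76, 25))), c(49, 49))
  expect_equal(unname(left_right_shift(mk(30, 80), mk(30, 80))), c(0, 0))
  expect_equal(unname(left_right_shift(mk(16, 67), mk(67, 16))), c(49, 49))
  expect_equal(unname(left_right_shift(mk(2, 50), mk(96, 50))), c(6, 0))
  sh <- left_right_shift(mk(NA, 40), mk(10, 90))
  expect_true(is.na(sh["St"]))
  expect_equal(unname(sh["Sw"]), 50)
})
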