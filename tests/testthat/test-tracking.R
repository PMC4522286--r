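test_that("rmse matches closed forms", {
  x <- seq(0, 2, length.out = 50)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x + 0.1, x), 0.1)
  expect_equal(rmse(x + rep(c(0.2, -0.2), 25), x), 0.2)
  # invariant to adding the same constant to both
  expect_equal(rmse(x + 5, x + 5 - 0.1), rmse(x, x - 0.1))
  expect_error(rmse(numeric(0), numeric(0)), "equal length|non-empty")
})

test_that("force onset detection finds steps and lags, undefined on flat traces", {
  rate <- 100
  flat <- rep(0, 500)
  expect_true(is.na(detect_force_onset(flat, rate, cue_time = 1)))

  step <- c(rep(0, 200), rep(2, 300))
  on <- detect_force_onset(step, rate, cue_time = 1.5)
  expect_lt(abs(on - 2.0), 0.03)

  # simulated lag: onset close to cue + lag (bias bounded by the smoothing
  # window)
  p <- build_tracking_protocol(target_forces = 2, trials_per_block = 2,
                               blocks_per_force = 1)
  par <- sim_params(tracking_noise_sd = 0, tracking_lag = 0.15,
                    release_tau = 0, baseline_offset = 0, seed = 1)
  sim <- simulate_tracking(p, par)
  res <- analyze_tracking(sim$recording, p)
  expect_true(all(abs(res$trials$force_onset_time - 0.15) <= 0.03))
})

test_that("release duration recovers linear and exponential releases", {
  rate <- 100
  # linear 2 N -> 0 over 1 s after a 1 s hold
  x <- c(rep(2, 100), seq(2, 0, length.out = 101), rep(0, 99))
  expect_equal(release_duration(x, rate, 2, hold_end = 1), 0.5,
               tolerance = 0.005 / 0.5)
  # exponential family
  for (tau in c(0.05, 0.1, 0.2, 0.5, 1.0)) {
    t <- seq(0, 6, by = 1 / rate)
    y <- ifelse(t < 1, 2, 2 * exp(-(t - 1) / tau))
    est <- release_duration(y, rate, 2, hold_end = 1)
    expect_lt(abs(est - tau * log(3)), 0.01)
  }
  # plateau above 25% of target: undefined
  z <- c(rep(2, 100), seq(2, 0.6, length.out = 101), rep(0.6, 199))
  expect_true(is.na(release_duration(z, rate, 2, hold_end = 1)))
})

test_that("hold statistics use the trimmed central window", {
  rate <- 100
  x <- c(rep(0, 100), rep(1, 400), rep(0, 100))
  hs <- hold_stats(x, rate, hold_start = 1, hold_end = 5)
  expect_equal(hs$mean_hold_force, 1)
  expect_equal(hs$cv_hold, 0)

  # alternating 0.9/1.1: mean 1, CV ~ 0.1
  x2 <- c(rep(0, 100), rep(c(0.9, 1.1), 200), rep(0, 100))
  hs2 <- hold_stats(x2, rate, 1, 5)
  expect_equal(hs2$mean_hold_force, 1)
  expect_equal(hs2$cv_hold, 0.1, tolerance = 2e-3)

  # trimmed window of a 4 s hold is exactly the central 3 s (300 samples)
  y <- numeric(600)
  y[window_start <- 151:450] <- 1  # mark exactly [1.5, 4.5)
  hs3 <- hold_stats(y, rate, 1, 5)
  expect_equal(hs3$mean_hold_force, 1)

  # non-positive mean: CV undefined
  hs4 <- hold_stats(rep(0, 600), rate, 1, 5)
  expect_true(is.na(hs4$cv_hold))
})

test_that("baseline force averages the 1.5-0.5 s pre-ramp window", {
  rate <- 100
  expect_equal(baseline_force(rep(0, 1000), rate, ramp_onset = 5), 0)
  expect_true(is.na(baseline_force(rep(0, 1000), rate, ramp_onset = 1)))
  # window is exactly 100 samples at 100 Hz: mark [3.5, 4.5) before onset 5
  x <- numeric(1000)
  x[351:450] <- 0.28
  expect_equal(baseline_force(x, rate, 5), 0.28)
  x[450] <- 100  # last sample inside the window
  expect_gt(baseline_force(x, rate, 5), 0.28)
})

test_that("trial segmentation partitions the timeline and flags truncation", {
  p <- build_tracking_protocol()
  rec <- force_recording(matrix(0, 18000, 4), 100)
  segs <- segment_trials(rec, p)
  expect_length(segs, 24)
  expect_equal(sum(lengths(lapply(segs, `[[`, "idx"))), 18000)

  p1 <- build_tracking_protocol(target_forces = 1, trials_per_block = 1,
                                blocks_per_force = 1)
  expect_length(segment_trials(force_recording(matrix(0, 750, 4), 100), p1), 1)

  short <- force_recording(matrix(0, 14000, 4), 100)
  expect_error(segment_trials(short, p), "missing trial")
  expect_error(segment_trials(short, p), "20, 21, 22, 23, 24")
})

test_that("noiseless simulated tracking yields exact metrics", {
  p <- build_tracking_protocol()
  par <- sim_params(tracking_noise_sd = 0, tracking_lag = 0, release_tau = 0,
                    baseline_offset = 0, seed = 1)
  res <- analyze_tracking(simulate_tracking(p, par)$recording, p)
  expect_equal(max(res$trials$rmse_ramp), 0, tolerance = 1e-10)
  expect_equal(max(res$trials$rmse_hold), 0, tolerance = 1e-10)
  expect_equal(res$trials$mean_hold_force, res$trials$target_force)
  expect_equal(res$trials$cv_hold, rep(0, 24))

  # exponential release: tau * ln 3 within one sample period
  par2 <- sim_params(tracking_noise_sd = 0, tracking_lag = 0,
                     release_tau = 0.2, baseline_offset = 0, seed = 1)
  res2 <- analyze_tracking(simulate_tracking(p, par2)$recording, p)
  expect_true(all(abs(res2$trials$release_duration - 0.2 * log(3)) <= 0.01))

  # elevated baseline is recovered by the baseline measure
  par3 <- sim_params(tracking_noise_sd = 0, tracking_lag = 0, release_tau = 0.05,
                     baseline_offset = 0.28, seed = 1)
  res3 <- analyze_tracking(simulate_tracking(p, par3)$recording, p)
  expect_equal(mean(res3$trials$baseline_force, na.rm = TRUE), 0.28,
               tolerance = 0.02)
  expect_true(is.na(res3$trials$baseline_force[1]))  # first trial undefined
})

test_that("summaries exclude undefined trials and report cell sizes", {
  p <- build_tracking_protocol()
  par <- sim_params(tracking_noise_sd = 0.04, tracking_lag = 0.12,
                    release_tau = 0.05, baseline_offset = 0, seed = 3)
  res <- analyze_tracking(simulate_tracking(p, par)$recording, p)
  s <- res$summary
  expect_equal(nrow(s), 2)
  expect_equal(s$n_baseline_force, c(11, 12))  # first trial has no baseline

  tr <- res$trials
  tr$release_duration[5] <- NA
  s2 <- summarize_tracking(tr)
  i <- which(s2$target_force == tr$target_force[5])
  expect_equal(s2$n_release_duration[i], sum(!is.na(tr$release_duration[
    tr$target_force == tr$target_force[5]])))
  got <- s2$release_duration[i]
  expect_equal(got, mean(tr$release_duration[tr$target_force == tr$target_force[5]],
                         na.rm = TRUE))
})
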