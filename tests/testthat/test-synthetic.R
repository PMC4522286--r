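test_that("sim_params validates its fields", {
  expect_error(sim_params(omission_prob = 1.5), "probability")
  expect_error(sim_params(tap_width = 0), "tap_width")
  E <- diag(4) * 2
  expect_error(sim_params(enslaving = E), "enslaving")
  expect_error(sim_params(enslaving = matrix(0.5, 4, 4)), "enslaving")
})

test_that("same seed gives identical traces, different seeds differ", {
  p <- build_tracking_protocol(target_forces = 1, trials_per_block = 2,
                               blocks_per_force = 1)
  a <- simulate_tracking(p, sim_params(seed = 5))
  b <- simulate_tracking(p, sim_params(seed = 5))
  c <- simulate_tracking(p, sim_params(seed = 6))
  expect_identical(a$recording$samples, b$recording$samples)
  expect_false(identical(a$recording$samples, c$recording$samples))

  pt <- build_single_tap_protocol(frequencies = 1, fingers = "index",
                                  taps_per_cued_phase = 5)
  a2 <- simulate_tapping(pt, sim_params(seed = 5))
  b2 <- simulate_tapping(pt, sim_params(seed = 5))
  expect_identical(a2$recording$samples, b2$recording$samples)
  expect_identical(a2$truth$taps, b2$truth$taps)
})

test_that("omission probability 1 silences the trace", {
  pt <- build_single_tap_protocol(frequencies = 2, fingers = "middle",
                                  taps_per_cued_phase = 10)
  par <- sim_params(omission_prob = 1, extra_tap_prob = 0, tap_noise_sd = 0,
                    baseline_offset = 0, seed = 3)
  sim <- simulate_tapping(pt, par)
  expect_equal(nrow(sim$truth$taps), 0)
  expect_lt(max(sim$recording$samples), 0.5)
  expect_equal(nrow(detect_taps(sim$recording)), 0)
})

test_that("jitter-free tapping reproduces the target rate exactly", {
  pt <- build_single_tap_protocol()
  sim <- simulate_tapping(pt, exact_tap_params(seed = 2))
  res <- analyze_single_tap(sim$recording, pt)
  expect_equal(res$pooled_rates$rate, res$pooled_rates$target_freq)
  expect_equal(res$slopes$slope, rep(1, 4))
})

test_that("presets have unit enslaving diagonals and the stated contrasts", {
  ctrl <- ffm_preset("control_like")
  par <- ffm_preset("paretic_like")
  expect_equal(unname(diag(ctrl$enslaving)), rep(1, 4))
  expect_equal(unname(diag(par$enslaving)), rep(1, 4))
  expect_gt(ctrl$max_rate, 3)
  expect_lt(par$max_rate, 3)
  expect_gt(par$baseline_offset, ctrl$baseline_offset)
  expect_gt(par$release_tau, ctrl$release_tau)
  # neighborhood gradient: coupling monotone non-increasing in digit distance
  for (lead in FFM_FINGERS) {
    d <- abs(match(FFM_FINGERS, FFM_FINGERS) - match(lead, FFM_FINGERS))
    cp <- par$enslaving[lead, ]
    ord <- order(d)
    expect_true(all(diff(cp[ord]) <= 1e-12))
  }
})

test_that("rate ceiling thins cue trains the analyzer can see", {
  pt <- build_single_tap_protocol(frequencies = 3, fingers = "index")
  par <- exact_tap_params(seed = 8, max_rate = 2)
  sim <- simulate_tapping(pt, par)
  res <- analyze_single_tap(sim$recording, pt)
  cued <- res$conditions[res$conditions$phase == "cued", ]
  un <- res$conditions[res$conditions$phase == "uncued", ]
  expect_lt(cued$rate, 3)
  # self-paced near the ceiling (the first uncued tap can be thinned by the
  # refractory gap from the last cued tap)
  expect_lte(un$rate, 2)
  expect_gte(un$rate, 1.8)
  expect_gt(nrow(sim$truth$thinned_cues), 0)
})

test_that("cohorts are reproducible and clinically coherent", {
  protos <- list(tracking = build_tracking_protocol(
                   target_forces = 1, trials_per_block = 2, blocks_per_force = 1),
                 single_tap = build_single_tap_protocol(taps_per_cued_phase = 3),
                 multi_tap = build_multi_tap_protocol(
                   one_finger_repeats = 1, two_finger_repeats = 1,
                   four_finger_repeats = 0, seed = 1))
  a <- make_cohort(3, 3, seed = 21, protocols = protos)
  b <- make_cohort(3, 3, seed = 21, protocols = protos)
  expect_identical(a$subjects[[2]]$recordings$tracking$samples,
                   b$subjects[[2]]$recordings$tracking$samples)
  expect_identical(a$subjects[[5]]$clinical, b$subjects[[5]]$clinical)

  empty <- make_cohort(0, 2, seed = 1, protocols = protos)
  expect_length(empty$subjects, 2)
  expect_true(all(vapply(empty$subjects, `[[`, "", "group") == "patient"))

  # severity up -> synthetic ARAT down
  big <- make_cohort(6, 6, seed = 22, protocols = protos)
  sev <- vapply(big$subjects, `[[`, 0, "severity")
  arat <- vapply(big$subjects, function(s) s$clinical$arat_total, 0)
  expect_lt(cor(sev, arat, method = "spearman"), 0)
})
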