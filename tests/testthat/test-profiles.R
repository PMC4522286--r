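fake_profile <- function(values, id = "X", group = NA_character_) {
  p <- compute_profile(subject_id = id, group = group)
  p$measures[] <- values
  p
}

test_that("control norms implement mean + 2 SD exactly", {
  profs <- list(fake_profile(rep(1, 6)), fake_profile(rep(3, 6)))
  norms <- compute_norms(profs)
  expect_equal(norms$mean, rep(2, 6))
  expect_equal(norms$sd, rep(sqrt(2), 6))
  expect_equal(norms$threshold, rep(2 + 2 * sqrt(2), 6))
  expect_equal(norms$threshold, norms$mean + 2 * norms$sd)
  expect_equal(attr(norms, "n_controls"), 2)

  zeros <- compute_norms(list(fake_profile(rep(0, 6)), fake_profile(rep(0, 6))))
  expect_equal(zeros$threshold, rep(0, 6))

  # a measure with < 2 defined values is unavailable
  p1 <- fake_profile(rep(1, 6))
  p1$measures["omission_rate"] <- NA
  n2 <- compute_norms(list(p1, fake_profile(rep(2, 6))))
  expect_true(is.na(n2$threshold[n2$measure == "omission_rate"]))
  expect_error(compute_norms(list()), "no control profiles")
})

test_that("pathology flags use a strict threshold and are monotone", {
  norms <- compute_norms(list(fake_profile(rep(1, 6)), fake_profile(rep(3, 6))))
  thr <- norms$threshold[1]
  at <- flag_pathology(fake_profile(rep(thr, 6)), norms)
  expect_false(any(at$flags))
  above <- flag_pathology(fake_profile(rep(thr + 1e-9, 6)), norms)
  expect_true(all(above$flags))
  below <- flag_pathology(fake_profile(rep(0, 6)), norms)
  expect_false(any(below$flags))
  # monotone: increasing a measure never clears its flag
  set.seed(1)
  for (i in 1:20) {
    v <- runif(6, 0, 10)
    f1 <- flag_pathology(fake_profile(v), norms)$flags
    f2 <- flag_pathology(fake_profile(v + runif(6, 0, 5)), norms)$flags
    expect_true(all(f2[f1]))
  }
})

test_that("clinical flags apply the 18 s Moberg cut-off", {
  expect_true(flag_clinical(list(moberg_s = c(19, 10)))$moberg_pathological)
  expect_false(flag_clinical(list(moberg_s = c(12, 10)))$moberg_pathological)
  expect_true(is.na(flag_clinical(list())$moberg_pathological))
})

test_that("correlation wrapper matches known coefficients", {
  expect_equal(correlate(1:10, (1:10)^3, "spearman")$coefficient, 1)
  r <- correlate(1:8, -2 * (1:8), "pearson")
  expect_equal(r$coefficient, -1)
  expect_equal(r$r_squared, 1)
  expect_equal(correlate(c(1, 2, 3, 4), c(1, 3, 2, 4), "spearman")$coefficient, 0.8)
  x <- c(2, 5, 1, 9, 4)
  expect_equal(correlate(x, x, "spearman")$coefficient, 1)
  expect_equal(correlate(x, x, "pearson")$coefficient, 1)
  expect_true(is.na(correlate(rep(1, 5), 1:5)$coefficient))
  expect_error(correlate(c(1, 2), c(3, 4)), "3 complete pairs")
  # missing pairs dropped, n reported
  r2 <- correlate(c(1, 2, NA, 4, 5), c(2, 4, 6, NA, 10), "pearson")
  expect_equal(r2$n, 3)
})

test_that("group comparison matches the pooled-variance formula", {
  x <- c(3.1, 2.8, 3.5, 3.0)
  y <- c(2.1, 2.4, 2.0, 2.6, 2.2)
  g <- group_compare(x, y)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(g$t_statistic, t_manual)
  expect_equal(g$df, length(x) + length(y) - 2)
  expect_equal(g$patients[["mean"]], mean(x))

  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)

  degen <- group_compare(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(is.na(degen$t_statistic))
  expect_match(degen$note, "variance")
})

test_that("profiles handle missing tasks and clean simulations", {
  p <- compute_profile()
  expect_true(all(is.na(p$measures)))

  proto_t <- build_tracking_protocol(trials_per_block = 2, blocks_per_force = 1)
  par <- sim_params(tracking_noise_sd = 0, tracking_lag = 0, release_tau = 0.02,
                    baseline_offset = 0, seed = 1)
  tr <- analyze_tracking(simulate_tracking(proto_t, par)$recording, proto_t)
  proto_s <- build_single_tap_protocol(taps_per_cued_phase = 5)
  st <- analyze_single_tap(simulate_tapping(proto_s, exact_tap_params(2))$recording,
                           proto_s)
  prof <- compute_profile(tracking = tr, single = st)
  expect_equal(unname(prof$measures["tracking_error"]), 0, tolerance = 1e-8)
  expect_equal(unname(prof$measures["one_minus_slope"]), 0, tolerance = 1e-10)
  expect_equal(unname(prof$measures["overflow_taps_1hz"]), 0)
  expect_true(is.na(prof$measures["omission_rate"]))
  expect_true(is.na(prof$measures["ueft_one_finger"]))

  # paretic rate ceiling shows up as a positive 1 - slope
  parp <- exact_tap_params(3, max_rate = 2.4)
  stp <- analyze_single_tap(simulate_tapping(proto_s, parp)$recording, proto_s)
  profp <- compute_profile(single = stp)
  expect_gt(profp$measures[["one_minus_slope"]], 0)
})
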