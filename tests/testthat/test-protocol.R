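test_that("tracking protocol reproduces the standard trial structure", {
  p <- build_tracking_protocol()
  expect_equal(nrow(p$trials), 24)
  expect_equal(length(unique(p$trials$block_index)), 4)
  expect_equal(sum(p$trials$target_force == 1), 12)
  expect_equal(sum(p$trials$target_force == 2), 12)
  expect_true(all(p$trials$ramp_duration == 1.5))
  expect_true(all(p$trials$hold_duration == 4))
  expect_true(all(p$trials$rest_duration == 2))
  expect_equal(p$total_duration, 24 * 7.5)
  # trials time-ordered and non-overlapping
  ends <- p$trials$ramp_start + 7.5
  expect_true(all(diff(p$trials$ramp_start) > 0))
  expect_true(all(p$trials$ramp_start[-1] >= ends[-24] - 1e-12))
})

test_that("tracking protocol honors custom parameters and rejects bad ones", {
  p <- build_tracking_protocol(target_forces = 1, trials_per_block = 2,
                               blocks_per_force = 1)
  expect_equal(nrow(p$trials), 2)
  expect_true(all(p$trials$target_force == 1))
  expect_error(build_tracking_protocol(ramp_s = 0), "ramp_s")
  expect_error(build_tracking_protocol(target_forces = c(1, -2)), "target_forces")
})

test_that("sequence protocol builds 15 trials with 50 cues at defaults", {
  for (lab in c("A", "B", "C")) {
    p <- build_sequence_protocol(lab)
    expect_equal(nrow(p$trials), 15)
    expect_equal(nrow(p$cues), 50)
    expect_equal(sum(p$trials$phase == "learning"), 10)
    # cue finger order within each trial matches the digit list
    first <- p$cues[p$cues$trial_index == 1, ]
    expect_equal(first$fingers, p$sequence$fingers)
    expect_equal(diff(first$time), rep(1, 4))
  }
  p0 <- build_sequence_protocol(cued_repeats = 0, recall_repeats = 1)
  expect_equal(nrow(p0$trials), 1)
  expect_equal(nrow(p0$cues), 0)
  expect_error(build_sequence_protocol(c(2, 3, 4)), "5 digits")
})

test_that("single-tap protocol orders conditions frequency-major", {
  p <- build_single_tap_protocol()
  expect_equal(length(unique(p$conditions$condition_index)), 12)
  expect_equal(nrow(p$conditions), 24)  # cued + uncued phases
  first12 <- p$conditions[p$conditions$phase == "cued", ]
  expect_equal(first12$target_freq, rep(c(1, 2, 3), each = 4))
  expect_equal(first12$finger, rep(FFM_FINGERS, 3))
  # cued phase spans taps/f seconds
  expect_equal(first12$end - first12$start, rep(15 / c(1, 2, 3), each = 4))
  # uncued phase has the same duration as its cued phase
  un <- p$conditions[p$conditions$phase == "uncued", ]
  expect_equal(un$end - un$start, first12$end - first12$start)

  p1 <- build_single_tap_protocol(frequencies = 2, fingers = "index")
  expect_equal(nrow(p1$cues), 15)
  expect_equal(diff(p1$cues$time), rep(0.5, 14))
  expect_error(build_single_tap_protocol(fingers = character(0)), "finger")
})

test_that("multi-tap protocol has the standard counts and balanced transitions", {
  p <- build_multi_tap_protocol()
  expect_equal(nrow(p$trials), 64)
  expect_equal(sum(p$trials$n_fingers == 1), 32)
  expect_equal(sum(p$trials$n_fingers == 2), 30)
  expect_equal(sum(p$trials$n_fingers == 4), 2)
  nf <- p$trials$n_fingers
  a <- sum(nf[-64] == 1 & nf[-1] == 2)
  b <- sum(nf[-64] == 2 & nf[-1] == 1)
  expect_lte(abs(a - b), 1)

  p1 <- build_multi_tap_protocol(one_finger_repeats = 1,
                                 two_finger_repeats = 0,
                                 four_finger_repeats = 0)
  expect_equal(sort(p1$trials$fingers), sort(FFM_FINGERS))
})

test_that("multi-tap order is seed-deterministic and seed-sensitive", {
  p1 <- build_multi_tap_protocol(seed = 42)
  p2 <- build_multi_tap_protocol(seed = 42)
  expect_identical(p1$trials$fingers, p2$trials$fingers)
  others <- vapply(43:46, function(s) {
    identical(build_multi_tap_protocol(seed = s)$trials$fingers,
              p1$trials$fingers)
  }, logical(1))
  expect_false(all(others))
  # multiset of configurations is invariant under the seed
  expect_equal(sort(build_multi_tap_protocol(seed = 99)$trials$fingers),
               sort(p1$trials$fingers))
})

test_that("cue times are strictly increasing and within the task duration", {
  for (p in list(build_sequence_protocol(), build_single_tap_protocol(),
                 build_multi_tap_protocol())) {
    expect_true(all(diff(p$cues$time) > 0) || p$task_kind == "single_tap")
    if (p$task_kind == "single_tap") expect_true(all(diff(p$cues$time) > 0))
    expect_true(all(p$cues$time < p$total_duration))
    expect_true(all(p$cues$time >= 0))
  }
})

test_that("protocols round-trip through JSON", {
  dir <- withr::local_tempdir()
  protos <- list(build_tracking_protocol(),
                 build_sequence_protocol("B"),
                 build_single_tap_protocol(),
                 build_multi_tap_protocol(seed = 7))
  for (p in protos) {
    path <- file.path(dir, paste0(p$task_kind, ".json"))
    write_protocol(p, path)
    q <- read_protocol(path)
    expect_equal(q$task_kind, p$task_kind)
    expect_equal(q$total_duration, p$total_duration)
    expect_equal(as.data.frame(q$trials), as.data.frame(p$trials))
    if (nrow(p$cues) > 0) {
      expect_equal(q$cues$time, p$cues$time)
      expect_equal(q$cues$fingers, p$cues$fingers)
    }
    if (!is.null(p$sequence)) expect_equal(q$sequence$digits, p$sequence$digits)
  }
})
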