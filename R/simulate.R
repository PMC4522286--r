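# Seedable generative model of force traces for all four tasks, with
# exported ground-truth events so every analysis stage can be checked
# against what was actually generated.

empty_taps_truth <- function() {
  data.frame(finger = character(0), time = numeric(0), amplitude = numeric(0),
             lead = logical(0), extra = logical(0), cue_index = integer(0),
             stringsAsFactors = FALSE)
}

new_ground_truth <- function(taps = empty_taps_truth(),
                             omitted = data.frame(cue_index = integer(0),
                                                  finger = character(0)),
                             thinned = data.frame(cue_index = integer(0),
                                                  finger = character(0)),
                             extras = data.frame(cue_index = integer(0),
                                                 finger = character(0),
                                                 time = numeric(0)),
                             trials = NULL) {
  structure(list(taps = taps, omitted_cues = omitted, thinned_cues = thinned,
                 injected_extras = extras, trials = trials),
            class = "ffm_ground_truth")
}

# Ideal trapezoid target profile of a tracking protocol on the grid of `t`.
tracking_target_profile <- function(protocol, t) {
  stopifnot(protocol$task_kind == "tracking")
  y <- numeric(length(t))
  for (j in seq_len(nrow(protocol$trials))) {
    tr <- protocol$trials[j, ]
    re <- tr$ramp_start + tr$ramp_duration
    he <- re + tr$hold_duration
    ramp <- t >= tr$ramp_start & t < re
    y[ramp] <- tr$target_force * (t[ramp] - tr$ramp_start) / tr$ramp_duration
    y[t >= re & t < he] <- tr$target_force
  }
  y
}

#' Simulate a finger force tracking session
#'
#' The lead-finger trace follows the trapezoid target delayed by the
#' visuo-motor lag, rides on the residual baseline offset, releases
#' exponentially (time constant `release_tau`) toward baseline at the end of
#' each hold, and carries white Gaussian force noise. Non-lead channels
#' receive the enslaving-scaled lead trace plus noise.
#'
#' @param protocol A tracking protocol from [build_tracking_protocol()].
#' @param params An [sim_params()] object (its `seed` fixes the realization).
#' @param finger Lead finger performing the task.
#' @param rate Sample rate of the generated trace, Hz.
#' @return A list with elements `recording` (an `ffm_recording`) and `truth`
#'   (an `ffm_ground_truth` carrying the per-trial generative values).
#' @export
simulate_tracking <- function(protocol, params, finger = "index",
                              rate = FFM_ANALYSIS_RATE) {
  stopifnot(inherits(protocol, "ffm_protocol"), protocol$task_kind == "tracking",
            inherits(params, "ffm_sim_params"))
  finger <- match.arg(finger, FFM_FINGERS)
  with_seed(params$seed, {
    n <- ceiling(protocol$total_duration * rate)
    t <- (seq_len(n) - 1) / rate
    b <- params$baseline_offset
    lag <- params$tracking_lag
    tau <- params$release_tau

    resp <- rep(b, n)
    trs <- protocol$trials
    for (j in seq_len(nrow(trs))) {
      tr <- trs[j, ]
      F <- tr$target_force
      rs <- tr$ramp_start + lag
      re <- rs + tr$ramp_duration
      he <- re + tr$hold_duration
      seg_end <- if (j < nrow(trs)) trs$ramp_start[j + 1] + lag else protocol$total_duration

      i_rs <- window_idx(rs, re, rate, n)
      r0 <- if (length(i_rs) > 0) resp[i_rs[1]] else b
      resp[i_rs] <- r0 + (F - r0) * (t[i_rs] - rs) / tr$ramp_duration
      i_h <- window_idx(re, he, rate, n)
      resp[i_h] <- F
      i_r <- window_idx(he, seg_end, rate, n)
      if (length(i_r) > 0) {
        resp[i_r] <- if (tau > 0) b + (F - b) * exp(-(t[i_r] - he) / tau) else b
      }
    }

    samples <- matrix(0, n, 4, dimnames = list(NULL, FFM_FINGERS))
    for (d in FFM_FINGERS) {
      gain <- params$enslaving[finger, d]
      samples[, d] <- gain * resp + stats::rnorm(n, 0, params$tracking_noise_sd)
    }

    meta <- list(subject_id = "sim", task_kind = "tracking",
                 lead_finger = finger, simulated = TRUE)
    truth_trials <- data.frame(trial_index = trs$trial_index,
                               target_force = trs$target_force,
                               lag = lag, release_tau = tau,
                               baseline_offset = b)
    list(recording = force_recording(samples, rate, meta = meta),
         truth = new_ground_truth(trials = truth_trials))
  })
}

# Raised-cosine pulse of amplitude `amp` and full width `width`, peak at
# `peak_time`, added in place to channel vector x.
add_pulse <- function(x, rate, peak_time, amp, width, n) {
  lo <- peak_time - width / 2
  i0 <- max(1L, floor(lo * rate) + 2L)
  i1 <- min(n, floor((peak_time + width / 2) * rate) + 1L)
  if (i1 < i0) return(x)
  tt <- (i0:i1 - 1) / rate
  x[i0:i1] <- x[i0:i1] + amp / 2 * (1 - cos(2 * pi * (tt - lo) / width))
  x
}

# Value the sampled trace will attain at the grid point nearest to the pulse
# peak (the continuous peak generally falls between samples).
sampled_peak <- function(peak_time, amp, width, rate) {
  delta <- abs(peak_time - round(peak_time * rate) / rate)
  if (delta >= width / 2) return(0)
  amp / 2 * (1 + cos(2 * pi * delta / width))
}

# Intended cue table for a tapping protocol: cued events from the protocol
# plus self-paced events for uncued single-tap phases and recall trials.
intended_cues <- function(protocol, params) {
  rows <- list()
  if (protocol$task_kind == "single_tap") {
    cues <- protocol$cues
    rows[[1]] <- data.frame(time = cues$time, fingers = cues$fingers,
                            gap = 1 / cues$nominal_rate,
                            trial_index = cues$trial_index,
                            stringsAsFactors = FALSE)
    un <- protocol$conditions[protocol$conditions$phase == "uncued", ]
    for (j in seq_len(nrow(un))) {
      sp <- max(1 / un$target_freq[j], 1 / params$max_rate)
      times <- seq(un$start[j], un$end[j] - 1e-9, by = sp)
      rows[[length(rows) + 1]] <- data.frame(
        time = times, fingers = un$finger[j], gap = sp,
        trial_index = un$condition_index[j], stringsAsFactors = FALSE)
    }
  } else if (protocol$task_kind == "sequential") {
    cues <- protocol$cues
    if (nrow(cues) > 0) {
      rows[[1]] <- data.frame(time = cues$time, fingers = cues$fingers,
                              gap = 1 / cues$nominal_rate,
                              trial_index = cues$trial_index,
                              stringsAsFactors = FALSE)
    }
    rec <- protocol$trials[protocol$trials$phase == "recall", ]
    sp <- 1 / min(params$max_rate, 2.5)  # self-paced recall tempo
    for (j in seq_len(nrow(rec))) {
      rows[[length(rows) + 1]] <- data.frame(
        time = rec$start[j] + (seq_along(protocol$sequence$fingers) - 1) * sp,
        fingers = protocol$sequence$fingers, gap = sp,
        trial_index = rec$trial_index[j], stringsAsFactors = FALSE)
    }
  } else {
    cues <- protocol$cues
    rows[[1]] <- data.frame(time = cues$time, fingers = cues$fingers,
                            gap = protocol$params$inter_trial_s,
                            trial_index = cues$trial_index,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$time), , drop = FALSE]
  out$cue_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Simulate a tapping session (sequential, single- or multi-finger)
#'
#' Each non-omitted cued finger produces a raised-cosine force pulse near the
#' cue time; enslaving adds scaled copies of each pulse to the other fingers,
#' and a pulse is recorded as a ground-truth tap event exactly when its
#' sampled trace peak exceeds the detection threshold. Intended taps arriving
#' faster than `max_rate` on a finger are dropped (rate saturation), uncued
#' single-tap phases and recall trials are tapped self-paced, and spontaneous
#' extra taps on non-target fingers are injected with `extra_tap_prob`.
#'
#' @inheritParams simulate_tracking
#' @param protocol A protocol with `task_kind` in
#'   `sequential`, `single_tap`, `multi_tap`.
#' @return A list with `recording` and `truth`; `truth$taps` lists every
#'   supra-threshold event (finger, peak time, sampled peak amplitude, lead /
#'   enslaved / extra provenance, cue index), and omitted, rate-thinned and
#'   injected events are reported separately.
#' @export
simulate_tapping <- function(protocol, params, rate = FFM_ANALYSIS_RATE) {
  stopifnot(inherits(protocol, "ffm_protocol"),
            protocol$task_kind %in% c("sequential", "single_tap", "multi_tap"),
            inherits(params, "ffm_sim_params"))
  with_seed(params$seed, {
    n <- ceiling(protocol$total_duration * rate)
    samples <- matrix(params$baseline_offset, n, 4,
                      dimnames = list(NULL, FFM_FINGERS))
    cues <- intended_cues(protocol, params)
    b <- params$baseline_offset
    thr <- params$detection_threshold

    taps <- list()
    omitted <- list()
    thinned <- list()
    extras <- list()
    last_tap <- stats::setNames(rep(-Inf, 4), FFM_FINGERS)
    min_gap <- 1 / params$max_rate

    for (k in seq_len(nrow(cues))) {
      cue <- cues[k, ]
      targets <- key_to_fingers(cue$fingers)
      jit <- stats::rnorm(1, 0, params$tap_jitter_sd)
      tp <- cue$time + params$reaction_s + jit

      active <- character(0)
      amps <- numeric(0)
      for (f in targets) {
        if (tp - last_tap[f] < min_gap - 1e-9) {
          thinned[[length(thinned) + 1]] <- data.frame(cue_index = k, finger = f)
        } else if (stats::runif(1) < params$omission_prob) {
          omitted[[length(omitted) + 1]] <- data.frame(cue_index = k, finger = f)
        } else {
          active <- c(active, f)
          amps <- c(amps, max(0.7, stats::rnorm(1, params$tap_amplitude,
                                                params$tap_amplitude_sd)))
          last_tap[f] <- tp
        }
      }

      if (length(active) > 0) {
        tot <- as.numeric(amps %*% params$enslaving[active, , drop = FALSE])
        names(tot) <- FFM_FINGERS
        for (d in FFM_FINGERS) {
          if (tot[d] <= 0) next
          samples[, d] <- add_pulse(samples[, d], rate, tp, tot[d],
                                    params$tap_width, n)
          peak <- b + sampled_peak(tp, tot[d], params$tap_width, rate)
          if (peak > thr) {
            # ground truth describes the sampled trace: the realized peak
            # sits on the nearest grid point
            taps[[length(taps) + 1]] <- data.frame(
              finger = d, time = round(tp * rate) / rate, amplitude = peak,
              lead = d %in% active, extra = FALSE, cue_index = k,
              stringsAsFactors = FALSE)
          }
        }
      }

      if (stats::runif(1) < params$extra_tap_prob) {
        pool <- setdiff(FFM_FINGERS, targets)
        if (length(pool) > 0) {
          f <- pool[sample.int(length(pool), 1)]
          te <- tp + stats::runif(1, 0.35, 0.65) * cue$gap
          amp <- max(0.7, stats::rnorm(1, params$tap_amplitude,
                                       params$tap_amplitude_sd))
          if (te < protocol$total_duration - params$tap_width) {
            samples[, f] <- add_pulse(samples[, f], rate, te, amp,
                                      params$tap_width, n)
            peak <- b + sampled_peak(te, amp, params$tap_width, rate)
            if (peak > thr) {
              taps[[length(taps) + 1]] <- data.frame(
                finger = f, time = round(te * rate) / rate, amplitude = peak,
                lead = FALSE,
                extra = TRUE, cue_index = k, stringsAsFactors = FALSE)
            }
            extras[[length(extras) + 1]] <- data.frame(cue_index = k, finger = f,
                                                       time = te)
          }
        }
      }
    }

    if (params$tap_noise_sd > 0) {
      samples <- samples + matrix(stats::rnorm(n * 4, 0, params$tap_noise_sd), n, 4)
    }

    bindrows <- function(lst, template) {
      if (length(lst) == 0) template else do.call(rbind, lst)
    }
    taps_df <- bindrows(taps, empty_taps_truth())
    taps_df <- taps_df[order(taps_df$time), , drop = FALSE]
    rownames(taps_df) <- NULL

    meta <- list(subject_id = "sim", task_kind = protocol$task_kind,
                 simulated = TRUE)
    list(recording = force_recording(samples, rate, meta = meta),
         truth = new_ground_truth(
           taps = taps_df,
           omitted = bindrows(omitted, data.frame(cue_index = integer(0),
                                                  finger = character(0))),
           thinned = bindrows(thinned, data.frame(cue_index = integer(0),
                                                  finger = character(0))),
           extras = bindrows(extras, data.frame(cue_index = integer(0),
                                                finger = character(0),
                                                time = numeric(0)))))
  })
}
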