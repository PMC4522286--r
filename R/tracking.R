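# Per-trial and per-subject analysis of the finger force tracking task:
# RMSE per phase, dF/dt onsets, 75-to-25% release duration, hold statistics
# and inter-trial baseline force. All measures that cannot be computed for a
# trial propagate as NA, never as zeros.

#' Root-mean-square error between trace and target
#'
#' @param trace,target Equal-length numeric vectors (forces in N).
#' @return `sqrt(mean((trace - target)^2))`.
#' @export
rmse <- function(trace, target) {
  if (length(trace) == 0 || length(trace) != length(target)) {
    stop("rmse: trace and target must be non-empty and of equal length")
  }
  sqrt(mean((trace - target)^2))
}

#' Detect a force onset as a dF/dt threshold crossing
#'
#' The trace is smoothed with a centered moving average and differentiated;
#' the onset is the first time at or after `cue_time` where the derivative
#' exceeds `threshold` (use a negative `threshold` for release onsets, where
#' the derivative must fall below it).
#'
#' @param trace Numeric force vector starting at t = 0.
#' @param rate Sample rate, Hz.
#' @param cue_time Search start, s.
#' @param window_end Search end, s (default: end of trace).
#' @param threshold Derivative threshold in N/s; sign selects direction.
#' @param smooth_s Moving-average window, s.
#' @return Onset time in seconds, or NA if no crossing occurs in the window.
#' @export
detect_force_onset <- function(trace, rate, cue_time, window_end = NULL,
                               threshold = 0.4, smooth_s = 0.05) {
  n <- length(trace)
  if (is.null(window_end)) window_end <- n / rate
  k <- max(1L, round(smooth_s * rate))
  sm <- stats::filter(trace, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- trace[is.na(sm)]
  d <- diff(as.numeric(sm)) * rate  # derivative at t = (i - 0.5)/rate
  idx <- which(if (threshold >= 0) d > threshold else d < threshold)
  if (length(idx) == 0) return(NA_real_)
  tt <- (idx - 0.5) / rate
  ok <- tt >= cue_time & tt < window_end
  if (!any(ok)) return(NA_real_)
  tt[which(ok)[1]]
}

#' Release duration: time from 75% to 25% of the target force
#'
#' Looks for the first downward crossing of 0.75 x target after `hold_end`,
#' then the first downward crossing of 0.25 x target after that; crossing
#' times use linear interpolation between samples. Returns NA when the force
#' never falls below 25% of target within the window (incomplete release).
#'
#' @param trace Numeric force vector starting at t = 0.
#' @param rate Sample rate, Hz.
#' @param target_force Target force of the trial, N.
#' @param hold_end End of the hold phase, s.
#' @param window_end End of the search window, s (default: end of trace).
#' @return Duration in seconds, or NA.
#' @export
release_duration <- function(trace, rate, target_force, hold_end,
                             window_end = NULL) {
  n <- length(trace)
  if (is.null(window_end)) window_end <- n / rate
  # include one sample before hold_end so an instantaneous release whose
  # crossings fall in the first inter-sample gap is still caught
  idx <- window_idx(hold_end - 1 / rate, window_end, rate, n)
  if (length(idx) < 2) return(NA_real_)
  t75 <- downward_crossing(trace, idx, 0.75 * target_force, rate)
  if (is.na(t75)) return(NA_real_)
  idx25 <- idx[idx >= floor(t75 * rate) + 1]
  t25 <- downward_crossing(trace, idx25, 0.25 * target_force, rate)
  if (is.na(t25)) return(NA_real_)
  t25 - t75
}

#' Hold-phase force statistics
#'
#' Mean force and coefficient of variation (sample SD / mean) over the hold
#' phase trimmed by `trim_s` at both ends, so a 4 s hold is summarized over
#' its central 3 s.
#'
#' @param trace Numeric force vector starting at t = 0.
#' @param rate Sample rate, Hz.
#' @param hold_start,hold_end Hold phase boundaries, s.
#' @param trim_s Trim at each end, s.
#' @return List with `mean_hold_force` and `cv_hold` (NA when the mean is
#'   not positive).
#' @export
hold_stats <- function(trace, rate, hold_start, hold_end, trim_s = 0.5) {
  idx <- window_idx(hold_start + trim_s, hold_end - trim_s, rate, length(trace))
  if (length(idx) < 2) stop("hold window too short after trimming")
  m <- mean(trace[idx])
  cv <- if (m > 0) stats::sd(trace[idx]) / m else NA_real_
  list(mean_hold_force = m, cv_hold = cv)
}

#' Inter-trial baseline force
#'
#' Mean force over the window from 1.5 s to 0.5 s before a ramp onset.
#' Undefined (NA) when less than 1.5 s of pre-ramp data exists (the first
#' trial of a run).
#'
#' @param trace Numeric force vector starting at t = 0.
#' @param rate Sample rate, Hz.
#' @param ramp_onset Ramp onset time of the trial, s.
#' @return Mean force in N, or NA.
#' @export
baseline_force <- function(trace, rate, ramp_onset) {
  if (ramp_onset < 1.5) return(NA_real_)
  idx <- window_idx(ramp_onset - 1.5, ramp_onset - 0.5, rate, length(trace))
  if (length(idx) == 0) return(NA_real_)
  mean(trace[idx])
}

#' Split a tracking recording into per-trial sample windows
#'
#' One half-open window per trial covering ramp + hold + rest; windows
#' partition the task timeline.
#'
#' @param rec An `ffm_recording` at the analysis rate.
#' @param protocol The tracking protocol used.
#' @return List of lists with `trial` (the protocol row) and `idx` (sample
#'   indices).
#' @export
segment_trials <- function(rec, protocol) {
  stopifnot(inherits(rec, "ffm_recording"), protocol$task_kind == "tracking")
  rate <- rec$sample_rate
  n <- n_samples(rec)
  trs <- protocol$trials
  ends <- trs$ramp_start + trs$ramp_duration + trs$hold_duration + trs$rest_duration
  short <- which(ends > n / rate + 1e-9)
  if (length(short) > 0) {
    stop("recording too short: missing trial(s) ",
         paste(trs$trial_index[short], collapse = ", "))
  }
  lapply(seq_len(nrow(trs)), function(j) {
    list(trial = trs[j, ],
         idx = window_idx(trs$ramp_start[j], ends[j], rate, n))
  })
}

#' Analyze a finger force tracking recording
#'
#' Computes the per-trial performance measures (phase-wise RMSE against the
#' commanded trapezoid target, dF/dt force and release onsets, 75-25%
#' release duration, hold mean and CV, inter-trial baseline force) and the
#' per-target-force summary of their trial means.
#'
#' @param rec An `ffm_recording` (resampled to 100 Hz if needed).
#' @param protocol The tracking protocol used.
#' @param finger Lead finger channel to analyze; defaults to the recording's
#'   `meta$lead_finger`, else "index".
#' @param onset_threshold dF/dt threshold in N/s for onset detection.
#' @param smooth_s Smoothing window for onset detection, s.
#' @return An `ffm_tracking_result`: list with `trials` (one row per trial)
#'   and `summary` (one row per target force, trial means and `n_trials_used`
#'   per measure).
#' @export
analyze_tracking <- function(rec, protocol, finger = NULL,
                             onset_threshold = 0.4, smooth_s = 0.05) {
  stopifnot(inherits(rec, "ffm_recording"), protocol$task_kind == "tracking")
  if (is.null(finger)) finger <- rec$meta$lead_finger
  if (is.null(finger)) finger <- "index"
  finger <- match.arg(finger, FFM_FINGERS)
  if (rec$sample_rate != FFM_ANALYSIS_RATE) {
    rec <- resample_to(rec, FFM_ANALYSIS_RATE)
  }
  rate <- rec$sample_rate
  x <- rec$samples[, finger]
  n <- length(x)
  t <- (seq_len(n) - 1) / rate
  segs <- segment_trials(rec, protocol)

  rows <- lapply(segs, function(seg) {
    tr <- seg$trial
    rs <- tr$ramp_start
    re <- rs + tr$ramp_duration
    he <- re + tr$hold_duration
    te <- he + tr$rest_duration
    F <- tr$target_force

    i_ramp <- window_idx(rs, re, rate, n)
    i_hold <- window_idx(re, he, rate, n)
    target_ramp <- F * (t[i_ramp] - rs) / tr$ramp_duration
    hs <- hold_stats(x, rate, re, he)
    onset <- detect_force_onset(x, rate, rs, window_end = he,
                                threshold = onset_threshold,
                                smooth_s = smooth_s)
    rel_on <- detect_force_onset(x, rate, he, window_end = te,
                                 threshold = -onset_threshold,
                                 smooth_s = smooth_s)
    data.frame(
      trial_index = tr$trial_index,
      target_force = F,
      rmse_ramp = rmse(x[i_ramp], target_ramp),
      rmse_hold = rmse(x[i_hold], rep(F, length(i_hold))),
      force_onset_time = if (is.na(onset)) NA_real_ else onset - rs,
      release_onset_time = if (is.na(rel_on)) NA_real_ else rel_on - he,
      release_duration = release_duration(x, rate, F, he, window_end = te),
      cv_hold = hs$cv_hold,
      mean_hold_force = hs$mean_hold_force,
      baseline_force = baseline_force(x, rate, rs)
    )
  })
  trials <- do.call(rbind, rows)
  structure(list(trials = trials,
                 summary = summarize_tracking(trials),
                 finger = finger),
            class = "ffm_tracking_result")
}

#' Summarize per-trial tracking metrics
#'
#' Trial means per target force; undefined (NA) trial values are excluded,
#' and the number of trials actually used is reported per measure. A cell
#' with no defined values is NA.
#'
#' @param trials Per-trial metrics data frame from [analyze_tracking()].
#' @return Data frame, one row per target force.
#' @export
summarize_tracking <- function(trials) {
  stopifnot(nrow(trials) >= 1)
  measures <- c("rmse_ramp", "rmse_hold", "force_onset_time",
                "release_onset_time", "release_duration", "cv_hold",
                "mean_hold_force", "baseline_force")
  out <- lapply(split(trials, trials$target_force), function(g) {
    row <- data.frame(target_force = g$target_force[1], n_trials = nrow(g))
    for (m in measures) {
      v <- g[[m]]
      row[[m]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      row[[paste0("n_", m)]] <- sum(!is.na(v))
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.ffm_tracking_result <- function(x, ...) {
  cat("<ffm_tracking_result>", x$finger, "finger,", nrow(x$trials), "trials\n")
  print(x$summary[, c("target_force", "n_trials", "rmse_ramp", "rmse_hold",
                      "release_duration", "mean_hold_force",
                      "baseline_force")], digits = 3)
  invisible(x)
}
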