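# Multi-finger tapping analysis: per-trial correctness of the response
# finger set against the cued configuration, omission and extra-tap errors,
# and the per-combination error matrix. Four-finger trials are parsed but
# excluded from all rates.

#' Score one multi-finger tapping trial
#'
#' The response set is the set of fingers with at least one detected tap in
#' the half-open window `(cue_time, cue_time + response_window]`. The trial
#' is correct iff the response set equals the target set; omissions are
#' target fingers absent from the response, extras are taps of non-target
#' fingers.
#'
#' @param taps Tap events (from [detect_taps()]).
#' @param target_fingers Character vector of the cued fingers.
#' @param cue_time Cue onset, s.
#' @param response_window Window length, s.
#' @return One-row data frame with `target`, `response`, `is_correct`,
#'   `n_omissions`, `n_extra_taps` and list columns `omissions`,
#'   `extra_fingers`.
#' @export
score_multi_trial <- function(taps, target_fingers, cue_time, response_window) {
  sel <- taps$peak_time > cue_time &
    taps$peak_time <= cue_time + response_window
  w <- taps[sel, , drop = FALSE]
  response <- unique(w$finger)
  omissions <- setdiff(target_fingers, response)
  extras <- w$finger[!w$finger %in% target_fingers]
  res <- data.frame(
    target = fingers_to_key(target_fingers),
    response = if (length(response) > 0) fingers_to_key(response) else "",
    is_correct = setequal(response, target_fingers),
    n_omissions = length(omissions),
    n_extra_taps = length(extras),
    stringsAsFactors = FALSE)
  res$omissions <- list(omissions)
  res$extra_fingers <- list(extras)
  res
}

multi_row_order <- function() {
  cf <- multi_tap_configs()
  vapply(c(cf$one, cf$two), fingers_to_key, "")
}

#' Analyze a multi-finger tapping recording
#'
#' Detects taps, scores each cue trial within its response window (cue onset
#' to the next cue onset, capped at the inter-trial interval) and summarizes
#' via [summarize_multi()].
#'
#' @param rec An `ffm_recording` at the analysis rate.
#' @param protocol The multi-tap protocol used.
#' @param response_window Response window length, s; default is the
#'   protocol's inter-trial interval.
#' @param threshold,refractory Passed to [detect_taps()].
#' @return An `ffm_multi_result`: `trials` (scored, incl. four-finger trials
#'   flagged `analyzed = FALSE`) and `summary` from [summarize_multi()].
#' @export
analyze_multi_tap <- function(rec, protocol, response_window = NULL,
                              threshold = 0.5, refractory = 0.1) {
  stopifnot(inherits(rec, "ffm_recording"), protocol$task_kind == "multi_tap")
  if (rec$sample_rate != FFM_ANALYSIS_RATE) rec <- resample_to(rec, FFM_ANALYSIS_RATE)
  taps <- detect_taps(rec, threshold, refractory)
  cues <- protocol$cues
  iti <- protocol$params$inter_trial_s
  rows <- lapply(seq_len(nrow(cues)), function(j) {
    gap <- if (j < nrow(cues)) cues$time[j + 1] - cues$time[j] else iti
    w <- if (is.null(response_window)) min(gap, iti) else response_window
    tf <- key_to_fingers(cues$fingers[j])
    cbind(data.frame(trial_index = cues$trial_index[j],
                     n_fingers = length(tf), analyzed = length(tf) <= 2,
                     stringsAsFactors = FALSE),
          score_multi_trial(taps, tf, cues$time[j], w))
  })
  trials <- do.call(rbind, rows)
  structure(list(trials = trials, summary = summarize_multi(trials),
                 taps = taps),
            class = "ffm_multi_result")
}

#' Summarize scored multi-finger tapping trials
#'
#' Success rate over one- and two-finger trials (overall and per condition
#' class), omission rate (omitted target-finger instances over cued
#' target-finger instances), unwanted extra-finger-tap (UEFT) totals split
#' by condition class, and the per-combination error matrix: for each of the
#' ten analyzed target combinations, the percentage of its trials in which
#' each finger tapped erroneously (target-coincident cells are NA).
#'
#' @param trials Scored trials from [analyze_multi_tap()] /
#'   [score_multi_trial()].
#' @return List with `success_rate`, `success_rate_one`, `success_rate_two`,
#'   `omission_rate`, `ueft_total`, `ueft_one_finger`, `ueft_two_finger`,
#'   `error_matrix` (10 x 4, percent) and `n_trials`.
#' @export
summarize_multi <- function(trials) {
  an <- trials[trials$analyzed, , drop = FALSE]
  stopifnot(nrow(an) >= 1)
  one <- an[an$n_fingers == 1, , drop = FALSE]
  two <- an[an$n_fingers == 2, , drop = FALSE]

  n_target_instances <- sum(an$n_fingers)
  n_omitted <- sum(an$n_omissions)

  rows <- multi_row_order()
  em <- matrix(NA_real_, length(rows), 4, dimnames = list(rows, FFM_FINGERS))
  for (key in rows) {
    g <- an[an$target == key, , drop = FALSE]
    if (nrow(g) == 0) next
    tf <- key_to_fingers(key)
    for (f in setdiff(FFM_FINGERS, tf)) {
      err <- vapply(g$extra_fingers, function(e) f %in% e, logical(1))
      em[key, f] <- 100 * mean(err)
    }
  }

  list(success_rate = mean(an$is_correct),
       success_rate_one = if (nrow(one) > 0) mean(one$is_correct) else NA_real_,
       success_rate_two = if (nrow(two) > 0) mean(two$is_correct) else NA_real_,
       omission_rate = if (n_target_instances > 0) n_omitted / n_target_instances else NA_real_,
       ueft_total = sum(an$n_extra_taps),
       ueft_one_finger = sum(one$n_extra_taps),
       ueft_two_finger = sum(two$n_extra_taps),
       error_matrix = em,
       n_trials = c(one_finger = nrow(one), two_finger = nrow(two),
                    excluded = sum(!trials$analyzed)))
}

#' @export
print.ffm_multi_result <- function(x, ...) {
  s <- x$summary
  cat("<ffm_multi_result>", sum(x$trials$analyzed), "analyzed trials\n")
  cat("  success", format(s$success_rate, digits = 3),
      " omission rate", format(s$omission_rate, digits = 3),
      " UEFT", s$ueft_total, "\n")
  invisible(x)
}
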