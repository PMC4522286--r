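# Single finger tapping analysis: per-condition rates and intervals for the
# lead finger, overflow versus unwanted classification of non-lead events,
# and the 1-3 Hz tapping-rate slope.

#' Score one single-tap condition phase
#'
#' Lead-finger events in the phase window give the tap count, achieved rate
#' and inter-tap intervals. Each non-lead event is an overflow tap when its
#' peak lies within `coincidence_window` of a lead tap peak, otherwise an
#' unwanted finger tap.
#'
#' @param taps Tap events (from [detect_taps()]).
#' @param finger Lead finger of the condition.
#' @param start,end Phase window, s (half-open).
#' @param coincidence_window Half-width of the lead-coincidence window, s.
#' @return One-row data frame: `n_taps`, `rate`, `mean_iti`, `iti_sd`,
#'   `n_overflow`, `n_unwanted`.
#' @export
score_single_tap <- function(taps, finger, start, end,
                             coincidence_window = 0.1) {
  sel <- taps$peak_time >= start & taps$peak_time < end
  w <- taps[sel, , drop = FALSE]
  lead <- w[w$finger == finger, , drop = FALSE]
  other <- w[w$finger != finger, , drop = FALSE]
  iti <- if (nrow(lead) >= 2) diff(sort(lead$peak_time)) else numeric(0)
  n_ov <- 0L
  n_uw <- 0L
  if (nrow(other) > 0) {
    coincident <- vapply(other$peak_time, function(tp) {
      nrow(lead) > 0 && min(abs(lead$peak_time - tp)) <= coincidence_window
    }, logical(1))
    n_ov <- sum(coincident)
    n_uw <- sum(!coincident)
  }
  data.frame(n_taps = nrow(lead),
             rate = nrow(lead) / (end - start),
             mean_iti = if (length(iti) > 0) mean(iti) else NA_real_,
             iti_sd = if (length(iti) > 1) stats::sd(iti) else NA_real_,
             n_overflow = n_ov,
             n_unwanted = n_uw)
}

#' Tapping-rate slope across target frequencies
#'
#' Ordinary least-squares fit of achieved tapping rate against target
#' frequency. A slope of 1 indicates veridical pacing; below 1, slowed
#' execution.
#'
#' @param target_freq Target frequencies, Hz.
#' @param rate Achieved rates, Hz (NA pairs dropped).
#' @return List with `slope` and `intercept` (NA with fewer than two
#'   distinct defined points).
#' @export
rate_slope <- function(target_freq, rate) {
  ok <- is.finite(target_freq) & is.finite(rate)
  x <- target_freq[ok]
  y <- rate[ok]
  if (length(x) < 2 || length(unique(x)) < 2) {
    return(list(slope = NA_real_, intercept = NA_real_))
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Analyze a single finger tapping recording
#'
#' Scores every (finger, frequency, phase) condition window, pools cued and
#' uncued phases into one achieved rate per (finger, frequency), and fits
#' the per-finger rate slope across target frequencies.
#'
#' @param rec An `ffm_recording` at the analysis rate.
#' @param protocol The single-tap protocol used.
#' @param coincidence_window Overflow coincidence half-window, s.
#' @param threshold,refractory Passed to [detect_taps()].
#' @return An `ffm_single_result`: `conditions` (per phase window),
#'   `pooled_rates` (per finger x frequency), `slopes` (per finger),
#'   `overflow_1hz` (overflow taps summed over the 1 Hz conditions) and
#'   totals `n_overflow`, `n_unwanted`.
#' @export
analyze_single_tap <- function(rec, protocol, coincidence_window = 0.1,
                               threshold = 0.5, refractory = 0.1) {
  stopifnot(inherits(rec, "ffm_recording"), protocol$task_kind == "single_tap")
  if (rec$sample_rate != FFM_ANALYSIS_RATE) rec <- resample_to(rec, FFM_ANALYSIS_RATE)
  taps <- detect_taps(rec, threshold, refractory)
  cond <- protocol$conditions
  scored <- lapply(seq_len(nrow(cond)), function(j) {
    cbind(cond[j, c("condition_index", "finger", "target_freq", "phase",
                    "start", "end")],
          score_single_tap(taps, cond$finger[j], cond$start[j], cond$end[j],
                           coincidence_window))
  })
  conditions <- do.call(rbind, scored)
  rownames(conditions) <- NULL

  pooled <- do.call(rbind, lapply(
    split(conditions, conditions[c("finger", "target_freq")], drop = TRUE),
    function(g) {
      data.frame(finger = g$finger[1], target_freq = g$target_freq[1],
                 n_taps = sum(g$n_taps),
                 rate = sum(g$n_taps) / sum(g$end - g$start),
                 stringsAsFactors = FALSE)
    }))
  rownames(pooled) <- NULL

  fingers <- unique(cond$finger)
  slopes <- do.call(rbind, lapply(fingers, function(f) {
    g <- pooled[pooled$finger == f, ]
    sl <- rate_slope(g$target_freq, g$rate)
    data.frame(finger = f, slope = sl$slope, intercept = sl$intercept,
               stringsAsFactors = FALSE)
  }))

  structure(list(conditions = conditions, pooled_rates = pooled,
                 slopes = slopes,
                 overflow_1hz = sum(conditions$n_overflow[conditions$target_freq == 1]),
                 n_overflow = sum(conditions$n_overflow),
                 n_unwanted = sum(conditions$n_unwanted),
                 taps = taps),
            class = "ffm_single_result")
}

#' @export
print.ffm_single_result <- function(x, ...) {
  cat("<ffm_single_result>\n")
  print(x$slopes, digits = 3)
  cat("  overflow taps:", x$n_overflow, "(", x$overflow_1hz, "at 1 Hz )",
      " unwanted:", x$n_unwanted, "\n")
  invisible(x)
}
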