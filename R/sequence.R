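# Scoring of the sequential finger tapping task: user tap strings are
# aligned to the 5-digit target by longest-common-subsequence, and a trial
# is correct only when the full ordered string matches exactly.

# LCS dynamic program returning length and matched user positions
# (canonical backtrace preferring later user positions on ties).
lcs_align <- function(u, v) {
  m <- length(u)
  n <- length(v)
  dp <- matrix(0L, m + 1, n + 1)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      dp[i + 1, j + 1] <- if (u[i] == v[j]) {
        dp[i, j] + 1L
      } else {
        max(dp[i, j + 1], dp[i + 1, j])
      }
    }
  }
  matched <- logical(m)
  i <- m
  j <- n
  while (i > 0 && j > 0) {
    if (u[i] == v[j] && dp[i + 1, j + 1] == dp[i, j] + 1L) {
      matched[i] <- TRUE
      i <- i - 1
      j <- j - 1
    } else if (dp[i, j + 1] >= dp[i + 1, j]) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(length = dp[m + 1, n + 1], matched = matched)
}

# Longest common substring (contiguous in both strings).
longest_common_run <- function(u, v) {
  m <- length(u)
  n <- length(v)
  if (m == 0 || n == 0) return(0L)
  best <- 0L
  prev <- integer(n + 1)
  for (i in seq_len(m)) {
    cur <- integer(n + 1)
    for (j in seq_len(n)) {
      if (u[i] == v[j]) {
        cur[j + 1] <- prev[j] + 1L
        if (cur[j + 1] > best) best <- cur[j + 1]
      }
    }
    prev <- cur
  }
  best
}

#' Score one sequential-tapping trial against the target sequence
#'
#' The ordered user tap string is aligned to the five-digit target by
#' longest common subsequence (LCS): correct taps are the LCS length,
#' missing taps the unmatched targets, extra taps the unmatched user taps,
#' and the longest correct run is the longest contiguous stretch matching
#' the target. A trial is correct only if the user string equals the target
#' exactly (five taps, no extras).
#'
#' @param user_fingers Ordered character vector of tapped fingers.
#' @param target An [ffm_sequence()] (or coercible).
#' @return One-row data frame (`n_user_taps`, `is_correct`, `n_correct_taps`,
#'   `n_missing`, `n_extra`, `longest_correct_run`) with the unmatched user
#'   fingers in the list column `extra_fingers`.
#' @export
score_sequence_trial <- function(user_fingers, target = "A") {
  target <- ffm_sequence(target)
  v <- target$fingers
  u <- as.character(user_fingers)
  al <- lcs_align(u, v)
  res <- data.frame(
    n_user_taps = length(u),
    is_correct = length(u) == length(v) && all(u == v),
    n_correct_taps = al$length,
    n_missing = length(v) - al$length,
    n_extra = length(u) - al$length,
    longest_correct_run = longest_common_run(u, v)
  )
  res$extra_fingers <- list(u[!al$matched])
  res
}

#' Analyze a sequential finger tapping recording
#'
#' Detects taps, scores each trial window against the target sequence and
#' summarizes per phase.
#'
#' @param rec An `ffm_recording` at the analysis rate.
#' @param protocol The sequential protocol used (carries the sequence).
#' @param threshold,refractory Passed to [detect_taps()].
#' @return An `ffm_sequence_result`: `trials` (one scored row per trial) and
#'   `summary` from [summarize_sequence()].
#' @export
analyze_sequence <- function(rec, protocol, threshold = 0.5, refractory = 0.1) {
  stopifnot(inherits(rec, "ffm_recording"), protocol$task_kind == "sequential")
  if (rec$sample_rate != FFM_ANALYSIS_RATE) rec <- resample_to(rec, FFM_ANALYSIS_RATE)
  taps <- detect_taps(rec, threshold, refractory)
  trs <- protocol$trials
  rows <- lapply(seq_len(nrow(trs)), function(j) {
    sel <- taps$peak_time >= trs$start[j] & taps$peak_time < trs$end[j]
    u <- taps$finger[sel][order(taps$peak_time[sel])]
    cbind(data.frame(trial_index = trs$trial_index[j], phase = trs$phase[j],
                     stringsAsFactors = FALSE),
          score_sequence_trial(u, protocol$sequence))
  })
  trials <- do.call(rbind, rows)
  structure(list(trials = trials, summary = summarize_sequence(trials),
                 taps = taps, sequence = protocol$sequence),
            class = "ffm_sequence_result")
}

#' Summarize scored sequential-tapping trials
#'
#' Per-phase success rate, error (unmatched) taps per finger, and the mean
#' number of correct taps in the first versus second half of the learning
#' phase.
#'
#' @param trials Scored trials from [analyze_sequence()] /
#'   [score_sequence_trial()], with `phase` and `trial_index` columns.
#' @return List with `success_rate` (per phase), `error_taps_per_finger`,
#'   `learning_halves` (mean correct taps, first and second half) and
#'   `n_trials`.
#' @export
summarize_sequence <- function(trials) {
  phases <- c("learning", "recall")
  success <- vapply(phases, function(p) {
    g <- trials[trials$phase == p, ]
    if (nrow(g) == 0) NA_real_ else mean(g$is_correct)
  }, numeric(1))

  extras <- unlist(trials$extra_fingers)
  err_per_finger <- vapply(FFM_FINGERS, function(f) sum(extras == f), numeric(1))

  learn <- trials[trials$phase == "learning", ]
  halves <- c(first = NA_real_, second = NA_real_)
  if (nrow(learn) >= 2) {
    learn <- learn[order(learn$trial_index), ]
    h <- floor(nrow(learn) / 2)
    halves <- c(first = mean(learn$n_correct_taps[seq_len(h)]),
                second = mean(learn$n_correct_taps[(h + 1):nrow(learn)]))
  }
  list(success_rate = success, error_taps_per_finger = err_per_finger,
       learning_halves = halves,
       n_trials = table(factor(trials$phase, levels = phases)))
}

#' @export
print.ffm_sequence_result <- function(x, ...) {
  cat("<ffm_sequence_result> sequence", x$sequence$label, "\n")
  cat("  success rate: learning",
      format(x$summary$success_rate["learning"], digits = 3),
      " recall", format(x$summary$success_rate["recall"], digits = 3), "\n")
  invisible(x)
}
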