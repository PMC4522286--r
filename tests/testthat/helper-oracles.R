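# Independent oracles used to cross-check the package implementations.
# These deliberately use brute-force enumeration / first-principles tallies
# rather than the package's own code paths.

# Greedy subsequence test: is `a` a subsequence of `b`?
is_subseq <- function(a, b) {
  j <- 1
  for (x in a) {
    while (j <= length(b) && b[j] != x) j <- j + 1
    if (j > length(b)) return(FALSE)
    j <- j + 1
  }
  TRUE
}

# Brute-force LCS length: enumerate every subsequence of u and keep the
# longest that is also a subsequence of v.
oracle_lcs <- function(u, v) {
  m <- length(u)
  if (m == 0) return(0L)
  best <- 0L
  for (mask in seq_len(2^m - 1)) {
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    if (sum(keep) <= best) next
    if (is_subseq(u[keep], v)) best <- sum(keep)
  }
  best
}

# Greedy bijective matching of detected event times to ground-truth times
# (same finger), within tolerance. Returns precision and recall.
match_events <- function(truth, detected, tol = 0.05) {
  n_match <- 0L
  for (f in unique(c(truth$finger, detected$finger))) {
    tt <- sort(truth$time[truth$finger == f])
    dd <- sort(detected$peak_time[detected$finger == f])
    used <- logical(length(dd))
    for (t1 in tt) {
      d <- abs(dd - t1)
      d[used] <- Inf
      if (length(d) > 0 && min(d) <= tol) {
        used[which.min(d)] <- TRUE
        n_match <- n_match + 1L
      }
    }
  }
  list(precision = if (nrow(detected) > 0) n_match / nrow(detected) else NA,
       recall = if (nrow(truth) > 0) n_match / nrow(truth) else NA)
}

# First-principles tally of multi-finger tapping outcomes directly from the
# simulator's ground-truth event list (never touching the trace or the
# detector): per analyzed trial, the response set is the set of fingers with
# an event in (cue, cue + window].
oracle_multi_tally <- function(truth, protocol) {
  cues <- protocol$cues
  iti <- protocol$params$inter_trial_s
  ev <- truth$taps
  n_correct <- 0L
  n_one <- 0L
  n_two <- 0L
  n_correct_one <- 0L
  n_correct_two <- 0L
  n_instances <- 0L
  n_omitted <- 0L
  ueft_one <- 0L
  ueft_two <- 0L
  combos <- character(0)
  err_counts <- list()
  trial_counts <- list()
  for (j in seq_len(nrow(cues))) {
    targets <- strsplit(cues$fingers[j], "+", fixed = TRUE)[[1]]
    if (length(targets) > 2) next
    t0 <- cues$time[j]
    gap <- if (j < nrow(cues)) cues$time[j + 1] - t0 else iti
    w <- min(gap, iti)
    sel <- ev$time > t0 & ev$time <= t0 + w
    resp <- ev$finger[sel]
    resp_set <- unique(resp)
    correct <- setequal(resp_set, targets)
    n_correct <- n_correct + correct
    if (length(targets) == 1) {
      n_one <- n_one + 1L
      n_correct_one <- n_correct_one + correct
      ueft_one <- ueft_one + sum(!resp %in% targets)
    } else {
      n_two <- n_two + 1L
      n_correct_two <- n_correct_two + correct
      ueft_two <- ueft_two + sum(!resp %in% targets)
    }
    n_instances <- n_instances + length(targets)
    n_omitted <- n_omitted + length(setdiff(targets, resp_set))
    key <- cues$fingers[j]
    if (is.null(trial_counts[[key]])) {
      trial_counts[[key]] <- 0L
      err_counts[[key]] <- setNames(rep(0L, 4), FFM_FINGERS)
    }
    trial_counts[[key]] <- trial_counts[[key]] + 1L
    for (f in setdiff(unique(resp_set), targets)) {
      err_counts[[key]][f] <- err_counts[[key]][f] + 1L
    }
  }
  em <- matrix(NA_real_, length(trial_counts), 4,
               dimnames = list(names(trial_counts), FFM_FINGERS))
  for (key in names(trial_counts)) {
    targets <- strsplit(key, "+", fixed = TRUE)[[1]]
    for (f in setdiff(FFM_FINGERS, targets)) {
      em[key, f] <- 100 * err_counts[[key]][f] / trial_counts[[key]]
    }
  }
  list(success_rate = n_correct / (n_one + n_two),
       success_rate_one = n_correct_one / n_one,
       success_rate_two = n_correct_two / n_two,
       omission_rate = n_omitted / n_instances,
       ueft_one_finger = ueft_one,
       ueft_two_finger = ueft_two,
       error_matrix = em)
}

# Noise-free, deterministic tapping parameters used in closure tests.
exact_tap_params <- function(seed = 1, ...) {
  defaults <- list(tap_jitter_sd = 0, tap_amplitude_sd = 0, tap_noise_sd = 0,
                   omission_prob = 0, extra_tap_prob = 0, baseline_offset = 0,
                   max_rate = 10, seed = seed)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}
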