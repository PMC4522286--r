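# Task protocol builders: machine-readable schedules for the four
# manipulandum tasks. All times are seconds from task start; phase intervals
# are half-open [start, end).

new_protocol <- function(task_kind, trials, cues, conditions, total_duration,
                         extra = list()) {
  p <- c(list(task_kind = task_kind,
              trials = trials,
              cues = cues,
              conditions = conditions,
              total_duration = total_duration),
         extra)
  class(p) <- "ffm_protocol"
  p
}

empty_cues <- function() {
  data.frame(cue_index = integer(0), time = numeric(0), fingers = character(0),
             kind = character(0), nominal_rate = numeric(0),
             trial_index = integer(0), stringsAsFactors = FALSE)
}

#' Build the finger force tracking protocol
#'
#' One tracking trial is a ramp (linear force increase), a hold (stable
#' force), an instantaneous release back to rest, and a resting phase.
#' Defaults reproduce the standard schedule: 24 trials in four blocks of six,
#' two blocks at 1 N and two at 2 N, with a 1.5 s ramp, 4 s hold and 2 s rest.
#'
#' @param target_forces Target force levels in newtons, one block group each.
#' @param trials_per_block Trials per block.
#' @param blocks_per_force Blocks per target force.
#' @param ramp_s,hold_s,rest_s Phase durations in seconds.
#' @return An `ffm_protocol` with `task_kind = "tracking"`.
#' @examples
#' p <- build_tracking_protocol()
#' nrow(p$trials)  # 24
#' @export
build_tracking_protocol <- function(target_forces = c(1, 2),
                                    trials_per_block = 6L,
                                    blocks_per_force = 2L,
                                    ramp_s = 1.5, hold_s = 4, rest_s = 2) {
  check_positive(target_forces, "target_forces")
  check_positive(trials_per_block, "trials_per_block")
  check_positive(blocks_per_force, "blocks_per_force")
  check_positive(ramp_s, "ramp_s")
  check_positive(hold_s, "hold_s")
  check_positive(rest_s, "rest_s")

  period <- ramp_s + hold_s + rest_s
  block_forces <- rep(target_forces, each = blocks_per_force)
  n_blocks <- length(block_forces)
  n_trials <- n_blocks * trials_per_block

  trials <- data.frame(
    trial_index = seq_len(n_trials),
    block_index = rep(seq_len(n_blocks), each = trials_per_block),
    target_force = rep(block_forces, each = trials_per_block),
    ramp_start = (seq_len(n_trials) - 1) * period,
    ramp_duration = ramp_s,
    hold_duration = hold_s,
    rest_duration = rest_s
  )
  conditions <- data.frame(target_force = target_forces,
                           n_trials = blocks_per_force * trials_per_block)
  new_protocol("tracking", trials, empty_cues(), conditions,
               total_duration = n_trials * period,
               extra = list(params = list(ramp_s = ramp_s, hold_s = hold_s,
                                          rest_s = rest_s)))
}

#' Five-tap finger sequences
#'
#' The three standard sequences are labelled A (2-5-3-4-2), B (4-3-5-2-4) and
#' C (3-2-4-5-3), with digits numbered 2 = index to 5 = little; each starts
#' and ends on the same digit. Custom sequences may be given as a numeric
#' vector of five digits in 2..5.
#'
#' @param x A label ("A", "B", "C") or a numeric vector of digits.
#' @param label Optional label for a custom sequence.
#' @return An `ffm_sequence`: list with `digits`, `fingers` and `label`.
#' @export
ffm_sequence <- function(x = "A", label = NULL) {
  builtin <- list(A = c(2, 5, 3, 4, 2), B = c(4, 3, 5, 2, 4), C = c(3, 2, 4, 5, 3))
  if (inherits(x, "ffm_sequence")) return(x)
  if (is.character(x) && length(x) == 1 && x %in% names(builtin)) {
    digits <- builtin[[x]]
    label <- x
  } else if (is.numeric(x)) {
    digits <- as.integer(x)
    if (is.null(label)) label <- paste(digits, collapse = "-")
  } else {
    stop("invalid parameter: sequence must be \"A\", \"B\", \"C\" or a digit vector")
  }
  if (length(digits) != 5) {
    stop("invalid parameter: a tap sequence must have exactly 5 digits")
  }
  structure(list(digits = digits, fingers = digit_to_finger(digits),
                 label = label),
            class = "ffm_sequence")
}

#' Build the sequential finger tapping protocol
#'
#' A five-tap sequence is repeated with visual cues (learning phase) and then
#' from memory (recall phase). Defaults: 10 cued repeats, 5 recall repeats,
#' cues at 1 Hz, one 5 s trial window per repeat.
#'
#' @param sequence An [ffm_sequence()] or anything coercible to one.
#' @param cued_repeats,recall_repeats Number of learning / recall trials.
#' @param cue_rate Visual cue presentation rate in Hz.
#' @param trial_s Trial window duration in seconds.
#' @return An `ffm_protocol` with `task_kind = "sequential"`.
#' @export
build_sequence_protocol <- function(sequence = "A", cued_repeats = 10L,
                                    recall_repeats = 5L, cue_rate = 1,
                                    trial_s = 5) {
  sequence <- ffm_sequence(sequence)
  check_positive(cued_repeats, "cued_repeats", strict = FALSE)
  check_positive(recall_repeats, "recall_repeats", strict = FALSE)
  check_positive(cue_rate, "cue_rate")
  check_positive(trial_s, "trial_s")
  if ((length(sequence$digits) - 1) / cue_rate >= trial_s) {
    stop("invalid parameter: trial_s too short for 5 cues at cue_rate")
  }

  n_trials <- cued_repeats + recall_repeats
  phase <- rep(c("learning", "recall"), c(cued_repeats, recall_repeats))
  trials <- data.frame(
    trial_index = seq_len(n_trials),
    phase = phase,
    start = (seq_len(n_trials) - 1) * trial_s,
    end = seq_len(n_trials) * trial_s,
    stringsAsFactors = FALSE
  )

  if (cued_repeats > 0) {
    per_trial <- lapply(seq_len(cued_repeats), function(i) {
      data.frame(time = trials$start[i] + (seq_along(sequence$fingers) - 1) / cue_rate,
                 fingers = sequence$fingers,
                 trial_index = i, stringsAsFactors = FALSE)
    })
    cues <- do.call(rbind, per_trial)
    cues <- data.frame(cue_index = seq_len(nrow(cues)), time = cues$time,
                       fingers = cues$fingers, kind = "visual_tap_cue",
                       nominal_rate = cue_rate, trial_index = cues$trial_index,
                       stringsAsFactors = FALSE)
  } else {
    cues <- empty_cues()
  }
  conditions <- data.frame(phase = c("learning", "recall"),
                           n_trials = c(cued_repeats, recall_repeats),
                           stringsAsFactors = FALSE)
  new_protocol("sequential", trials, cues, conditions,
               total_duration = n_trials * trial_s,
               extra = list(sequence = sequence,
                            params = list(cue_rate = cue_rate, trial_s = trial_s)))
}

#' Build the single finger tapping protocol
#'
#' Repetitive tapping with one finger, paced by an auditory metronome (cued
#' phase) and then continued unpaced for an equal duration (uncued phase).
#' Conditions are ordered frequency-major, finger-minor: index through little
#' at the first rate, then at the next rate, and so on.
#'
#' @param frequencies Target tapping rates in Hz (default 1, 2, 3).
#' @param fingers Ordered lead fingers (default all four).
#' @param taps_per_cued_phase Number of metronome cues per cued phase.
#' @return An `ffm_protocol` with `task_kind = "single_tap"`.
#' @export
build_single_tap_protocol <- function(frequencies = c(1, 2, 3),
                                      fingers = FFM_FINGERS,
                                      taps_per_cued_phase = 15L) {
  check_positive(frequencies, "frequencies")
  if (length(fingers) == 0) stop("invalid parameter: empty finger list")
  fingers <- match.arg(fingers, FFM_FINGERS, several.ok = TRUE)
  if (taps_per_cued_phase < 1) {
    stop("invalid parameter: taps_per_cued_phase must be >= 1")
  }
  n <- as.integer(taps_per_cued_phase)

  cond_rows <- list()
  cue_rows <- list()
  t0 <- 0
  ci <- 0L
  for (f in frequencies) {
    phase_dur <- n / f
    for (fg in fingers) {
      ci <- ci + 1L
      cond_rows[[length(cond_rows) + 1]] <- data.frame(
        condition_index = ci, finger = fg, target_freq = f,
        phase = c("cued", "uncued"),
        start = c(t0, t0 + phase_dur),
        end = c(t0 + phase_dur, t0 + 2 * phase_dur),
        n_cues = c(n, 0L), stringsAsFactors = FALSE)
      cue_rows[[length(cue_rows) + 1]] <- data.frame(
        time = t0 + (0:(n - 1)) / f, fingers = fg, kind = "auditory_metronome",
        nominal_rate = f, trial_index = ci, stringsAsFactors = FALSE)
      t0 <- t0 + 2 * phase_dur
    }
  }
  conditions <- do.call(rbind, cond_rows)
  cues <- do.call(rbind, cue_rows)
  cues <- data.frame(cue_index = seq_len(nrow(cues)), cues,
                     stringsAsFactors = FALSE)
  new_protocol("single_tap", trials = conditions, cues = cues,
               conditions = conditions, total_duration = t0,
               extra = list(params = list(taps_per_cued_phase = n)))
}

multi_tap_configs <- function() {
  one <- as.list(FFM_FINGERS)
  two <- utils::combn(FFM_FINGERS, 2, simplify = FALSE)
  four <- list(FFM_FINGERS)
  list(one = one, two = two, four = four)
}

#' Build the multi-finger tapping protocol
#'
#' Visually cued taps of one-, two- and four-finger configurations in
#' pseudo-random order. Defaults give 32 one-finger, 30 two-finger and 2
#' four-finger cues (64 trials). The order is a seeded permutation chosen so
#' that the numbers of one-to-two and two-to-one finger transitions differ by
#' at most one (rejection sampling with a retry cap; if the counts make the
#' constraint infeasible, the best order found is used with a warning).
#'
#' @param one_finger_repeats Repeats of each of the 4 one-finger configurations.
#' @param two_finger_repeats Repeats of each of the 6 two-finger configurations.
#' @param four_finger_repeats Repeats of the four-finger configuration.
#' @param inter_trial_s Interval between successive cues, seconds.
#' @param seed Integer seed for the pseudo-random order.
#' @param max_tries Retry cap for the transition-balance search.
#' @return An `ffm_protocol` with `task_kind = "multi_tap"`.
#' @export
build_multi_tap_protocol <- function(one_finger_repeats = 8L,
                                     two_finger_repeats = 5L,
                                     four_finger_repeats = 2L,
                                     inter_trial_s = 4.375, seed = 1L,
                                     max_tries = 10000L) {
  check_positive(one_finger_repeats, "one_finger_repeats", strict = FALSE)
  check_positive(two_finger_repeats, "two_finger_repeats", strict = FALSE)
  check_positive(four_finger_repeats, "four_finger_repeats", strict = FALSE)
  check_positive(inter_trial_s, "inter_trial_s")

  cf <- multi_tap_configs()
  keys <- c(rep(vapply(cf$one, fingers_to_key, ""), each = one_finger_repeats),
            rep(vapply(cf$two, fingers_to_key, ""), each = two_finger_repeats),
            rep(vapply(cf$four, fingers_to_key, ""), each = four_finger_repeats))
  if (length(keys) == 0) stop("invalid parameter: all repeat counts are zero")
  n_fingers <- lengths(strsplit(keys, "+", fixed = TRUE))

  imbalance <- function(nf) {
    a <- sum(nf[-length(nf)] == 1 & nf[-1] == 2)
    b <- sum(nf[-length(nf)] == 2 & nf[-1] == 1)
    abs(a - b)
  }
  ord <- with_seed(seed, {
    best <- NULL
    best_imb <- Inf
    tries <- 0L
    repeat {
      cand <- sample.int(length(keys))
      imb <- imbalance(n_fingers[cand])
      if (imb < best_imb) {
        best <- cand
        best_imb <- imb
      }
      tries <- tries + 1L
      if (best_imb <= 1 || tries >= max_tries) break
    }
    if (best_imb > 1) {
      warning("transition balance infeasible within retry cap; ",
              "best-effort order with imbalance ", best_imb)
    }
    best
  })
  keys <- keys[ord]
  n_fingers <- n_fingers[ord]

  n_trials <- length(keys)
  trials <- data.frame(
    trial_index = seq_len(n_trials),
    fingers = keys,
    n_fingers = n_fingers,
    start = (seq_len(n_trials) - 1) * inter_trial_s,
    end = seq_len(n_trials) * inter_trial_s,
    stringsAsFactors = FALSE
  )
  cues <- data.frame(cue_index = seq_len(n_trials), time = trials$start,
                     fingers = keys, kind = "visual_tap_cue",
                     nominal_rate = NA_real_, trial_index = trials$trial_index,
                     stringsAsFactors = FALSE)
  conditions <- data.frame(
    class = c("one_finger", "two_finger", "four_finger"),
    n_trials = c(sum(n_fingers == 1), sum(n_fingers == 2), sum(n_fingers == 4))
  )
  new_protocol("multi_tap", trials, cues, conditions,
               total_duration = n_trials * inter_trial_s,
               extra = list(params = list(inter_trial_s = inter_trial_s,
                                          seed = as.integer(seed))))
}

#' @export
print.ffm_protocol <- function(x, ...) {
  cat("<ffm_protocol>", x$task_kind, "\n")
  cat("  trials:", nrow(x$trials), " cues:", nrow(x$cues),
      " duration:", format(x$total_duration), "s\n")
  invisible(x)
}

#' Serialize / deserialize a task protocol as JSON
#'
#' The document carries a `schema_version` field and round-trips all schedule
#' tables bit-stably at full double precision.
#'
#' @param protocol An `ffm_protocol`.
#' @param path File path.
#' @return `read_protocol` returns the reconstructed `ffm_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "ffm_protocol"))
  obj <- list(schema_version = 1L,
              task_kind = protocol$task_kind,
              total_duration = protocol$total_duration,
              trials = protocol$trials,
              cues = protocol$cues,
              conditions = protocol$conditions,
              params = protocol$params)
  if (!is.null(protocol$sequence)) {
    obj$sequence <- list(digits = protocol$sequence$digits,
                         label = protocol$sequence$label)
  }
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

json_df <- function(x, template) {
  if (is.null(x) || length(x) == 0) return(template)
  as.data.frame(x, stringsAsFactors = FALSE)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  extra <- list(params = obj$params)
  if (!is.null(obj$sequence)) {
    extra$sequence <- ffm_sequence(obj$sequence$digits, label = obj$sequence$label)
  }
  new_protocol(obj$task_kind,
               trials = json_df(obj$trials, data.frame()),
               cues = json_df(obj$cues, empty_cues()),
               conditions = json_df(obj$conditions, data.frame()),
               total_duration = obj$total_duration,
               extra = extra)
}
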