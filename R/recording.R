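# Four-channel force recording container and delimited-text + JSON sidecar
# I/O. Trace files are comma-separated, '.' decimal, UTF-8, one header row,
# with an optional time column `t` (seconds); forces are in newtons.

#' Construct a four-channel force recording
#'
#' @param samples Numeric matrix (or data frame) with one column per finger.
#'   Columns are reordered to (index, middle, ring, little) if named;
#'   unnamed columns are assumed already in that order.
#' @param sample_rate Sampling rate in Hz.
#' @param meta Named list of recording metadata (subject_id, group, hand,
#'   task_kind, digit_map, ...). Free-form; see [read_recording()].
#' @param start_time Time of the first sample, seconds (0 by convention).
#' @return An object of class `ffm_recording`.
#' @export
force_recording <- function(samples, sample_rate, meta = list(), start_time = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (ncol(samples) != 4) {
    stop("samples must have 4 force channels, got ", ncol(samples))
  }
  if (nrow(samples) < 1) stop("samples must have at least one row")
  if (!is.null(colnames(samples))) {
    idx <- match(FFM_FINGERS, colnames(samples))
    if (anyNA(idx)) {
      stop("missing channel: ", paste(FFM_FINGERS[is.na(idx)], collapse = ", "))
    }
    samples <- samples[, idx, drop = FALSE]
  }
  colnames(samples) <- FFM_FINGERS
  check_positive(sample_rate, "sample_rate")
  structure(list(samples = samples, sample_rate = sample_rate,
                 start_time = start_time, meta = meta),
            class = "ffm_recording")
}

n_samples <- function(rec) nrow(rec$samples)

rec_times <- function(rec) {
  rec$start_time + (seq_len(n_samples(rec)) - 1) / rec$sample_rate
}

rec_duration <- function(rec) n_samples(rec) / rec$sample_rate

#' @export
print.ffm_recording <- function(x, ...) {
  cat("<ffm_recording>", n_samples(x), "samples x 4 fingers @",
      x$sample_rate, "Hz (", format(rec_duration(x), digits = 4), "s )\n")
  if (!is.null(x$meta$subject_id)) {
    cat("  subject:", x$meta$subject_id,
        if (!is.null(x$meta$task_kind)) paste(" task:", x$meta$task_kind), "\n")
  }
  invisible(x)
}

#' @export
plot.ffm_recording <- function(x, fingers = FFM_FINGERS, xlim = NULL, ...) {
  tt <- rec_times(x)
  if (is.null(xlim)) xlim <- range(tt)
  cols <- c(index = "firebrick", middle = "steelblue",
            ring = "forestgreen", little = "darkturquoise")
  graphics::matplot(tt, x$samples[, fingers, drop = FALSE], type = "l",
                    lty = 1, col = cols[fingers], xlab = "time (s)",
                    ylab = "force (N)", xlim = xlim, ...)
  graphics::legend("topright", legend = fingers, col = cols[fingers],
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Validate a force recording against the sensor model
#'
#' Reports (rather than throws) problems: non-finite samples and forces
#' outside the sensor range. The nominal sensor range is 0-9 N; a tolerance
#' of 0.5 N is allowed on both sides for noise and transient overshoot, and
#' out-of-range values are warnings, not errors, since impaired subjects may
#' exceed the nominal range transiently.
#'
#' @param rec An `ffm_recording`.
#' @param sensor_range Acceptable force range in N after tolerance.
#' @return A data frame of issues (severity, code, message, sample, channel);
#'   zero rows if the recording is clean.
#' @export
validate_recording <- function(rec, sensor_range = c(-0.5, 9.5)) {
  stopifnot(inherits(rec, "ffm_recording"))
  issues <- list()
  add <- function(severity, code, message, sample = NA_integer_,
                  channel = NA_character_) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, code = code, message = message,
      sample = sample, channel = channel, stringsAsFactors = FALSE)
  }
  for (ch in FFM_FINGERS) {
    x <- rec$samples[, ch]
    bad <- which(!is.finite(x))
    for (k in bad) {
      add("error", "non_finite", paste0("non-finite force at sample ", k,
                                        " (", ch, ")"), k, ch)
    }
    out <- which(is.finite(x) & (x < sensor_range[1] | x > sensor_range[2]))
    for (k in out) {
      add("warning", "out_of_range",
          paste0("force ", format(x[k], digits = 4), " N out of sensor range at sample ",
                 k, " (", ch, ")"), k, ch)
    }
  }
  if (length(issues) == 0) {
    return(data.frame(severity = character(0), code = character(0),
                      message = character(0), sample = integer(0),
                      channel = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Read a force recording from a trace file and JSON sidecar
#'
#' The trace file must be delimited text with a header row naming the four
#' force columns (finger names, or sensor channel names mapped to fingers by
#' `digit_map` in the sidecar) and optionally a time column `t` in seconds.
#' The sample rate is taken from the sidecar when declared, otherwise
#' inferred from a (required, uniformly increasing) time column.
#'
#' @param trace_path Path to the delimited-text trace.
#' @param meta_path Path to the JSON sidecar.
#' @return A validated `ffm_recording`; channel order normalized to
#'   (index, middle, ring, little).
#' @export
read_recording <- function(trace_path, meta_path) {
  side <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(trace_path, check.names = FALSE)

  digit_map <- side$meta$digit_map
  if (!is.null(digit_map)) {
    digit_map <- unlist(digit_map)
    if (!setequal(unname(digit_map), FFM_FINGERS)) {
      stop("format error: digit_map must be a bijection onto the four fingers")
    }
    present <- intersect(names(digit_map), names(df))
    names(df)[match(present, names(df))] <- unname(digit_map[present])
  }
  missing <- setdiff(FFM_FINGERS, names(df))
  if (length(missing) > 0) {
    stop("format error: missing channel ", paste(missing, collapse = ", "))
  }

  for (ch in FFM_FINGERS) {
    bad <- which(!is.finite(df[[ch]]))
    if (length(bad) > 0) {
      stop("format error: non-finite force in column '", ch, "' at row ", bad[1])
    }
  }

  sample_rate <- side$sample_rate
  start_time <- if (!is.null(side$start_time)) side$start_time else 0
  if ("t" %in% names(df)) {
    dt <- diff(df$t)
    if (nrow(df) > 1 && any(dt <= 0)) {
      stop("format error: non-monotonic time column at row ",
           which(dt <= 0)[1] + 1)
    }
    if (is.null(sample_rate)) {
      if (nrow(df) < 2) stop("format error: cannot infer sample rate from one sample")
      if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
        stop("format error: non-uniform time column and no declared sample_rate")
      }
      sample_rate <- 1 / stats::median(dt)
    }
    start_time <- df$t[1]
  } else if (is.null(sample_rate)) {
    stop("format error: no time column and no declared sample_rate in sidecar")
  }

  meta <- side$meta
  if (is.null(meta)) meta <- list()
  if (!is.null(digit_map)) meta$digit_map <- as.list(digit_map)
  if (!is.null(side$clinical)) meta$clinical <- side$clinical
  force_recording(as.matrix(df[FFM_FINGERS]), sample_rate = sample_rate,
                  meta = meta, start_time = start_time)
}

#' Write a force recording to a trace file and JSON sidecar
#'
#' Inverse of [read_recording()]: comma-separated trace with columns
#' `t,index,middle,ring,little` and a versioned JSON sidecar holding the
#' sample rate and metadata. Given identical input the output is bit-stable.
#'
#' @param rec An `ffm_recording`.
#' @param trace_path,meta_path Output paths.
#' @export
write_recording <- function(rec, trace_path, meta_path) {
  stopifnot(inherits(rec, "ffm_recording"))
  df <- data.frame(t = rec_times(rec), rec$samples, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   trace_path, row.names = FALSE, quote = FALSE)
  side <- list(schema_version = 1L,
               sample_rate = rec$sample_rate,
               start_time = rec$start_time,
               meta = rec$meta)
  jsonlite::write_json(side, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(trace_path)
}

#' Down-sample a recording to the analysis rate
#'
#' Anti-aliased decimation: a zero-phase 4th-order Butterworth low-pass at
#' 90% of the target Nyquist frequency, followed by linear interpolation onto
#' the uniform target grid. All analyses in this package expect 100 Hz.
#' Upsampling is not supported.
#'
#' @param rec An `ffm_recording`.
#' @param target_rate Target rate in Hz, `<= rec$sample_rate`.
#' @return The resampled `ffm_recording` (identical object if the rate
#'   already matches).
#' @export
resample_to <- function(rec, target_rate = FFM_ANALYSIS_RATE) {
  stopifnot(inherits(rec, "ffm_recording"))
  check_positive(target_rate, "target_rate")
  if (target_rate > rec$sample_rate) {
    stop("invalid parameter: upsampling (", rec$sample_rate, " -> ",
         target_rate, " Hz) is not supported")
  }
  if (target_rate == rec$sample_rate) return(rec)

  n <- n_samples(rec)
  x <- rec$samples
  # Low-pass below the target Nyquist. filtfilt needs a reasonable signal
  # length; very short traces are interpolated without filtering.
  if (n >= 30) {
    bf <- signal::butter(4, 0.9 * target_rate / rec$sample_rate)
    # filter around the mean so a constant signal passes through exactly
    x <- apply(x, 2, function(col) {
      mu <- mean(col)
      signal::filtfilt(bf, col - mu) + mu
    })
  }
  t_old <- rec_times(rec)
  n_out <- floor((n - 1) / rec$sample_rate * target_rate) + 1
  t_new <- rec$start_time + (seq_len(n_out) - 1) / target_rate
  y <- apply(x, 2, function(col) {
    stats::approx(t_old, col, xout = t_new, rule = 2)$y
  })
  y <- matrix(y, ncol = 4, dimnames = list(NULL, FFM_FINGERS))
  force_recording(y, sample_rate = target_rate, meta = rec$meta,
                  start_time = rec$start_time)
}
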