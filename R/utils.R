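# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Canonical key for a finger set, e.g. "index+ring". Order follows channel
# order so keys are comparable with setequal-free string equality.
fingers_to_key <- function(fingers) {
  idx <- match(fingers, FFM_FINGERS)
  if (anyNA(idx)) {
    stop("unknown finger(s): ", paste(fingers[is.na(idx)], collapse = ", "))
  }
  paste(FFM_FINGERS[sort(unique(idx))], collapse = "+")
}

key_to_fingers <- function(key) {
  if (is.na(key) || !nzchar(key)) return(character(0))
  strsplit(key, "+", fixed = TRUE)[[1]]
}

# Digit number (2..5) <-> finger name.
digit_to_finger <- function(digit) {
  if (any(!digit %in% 2:5)) stop("digits must be in 2..5 (2 = index, 5 = little)")
  FFM_FINGERS[digit - 1L]
}

finger_to_digit <- function(finger) {
  idx <- match(finger, FFM_FINGERS)
  if (anyNA(idx)) stop("unknown finger(s): ", paste(finger[is.na(idx)], collapse = ", "))
  idx + 1L
}

# Anatomical distance between two fingers (0..3).
finger_distance <- function(a, b) {
  abs(match(a, FFM_FINGERS) - match(b, FFM_FINGERS))
}

check_positive <- function(x, name, strict = TRUE) {
  if (length(x) == 0 || any(!is.finite(x)) || (strict && any(x <= 0)) ||
      (!strict && any(x < 0))) {
    stop("invalid parameter: `", name, "` must be ",
         if (strict) "> 0" else ">= 0", call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop("invalid parameter: `", name, "` must be a probability in [0, 1]",
         call. = FALSE)
  }
  invisible(x)
}

# Sample indices (1-based) covering the half-open time window [start, end)
# of a trace sampled at `rate` starting at t = 0.
window_idx <- function(start, end, rate, n) {
  i0 <- max(1L, floor(start * rate + 1e-9) + 1L)
  i1 <- min(n, ceiling(end * rate - 1e-9))
  if (i1 < i0) return(integer(0))
  i0:i1
}

# First downward crossing of `level` in x[idx] (idx contiguous); returns the
# linearly interpolated crossing time in seconds, or NA if none.
downward_crossing <- function(x, idx, level, rate) {
  if (length(idx) < 2) return(NA_real_)
  xs <- x[idx]
  hit <- which(xs[-length(xs)] >= level & xs[-1] < level)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  frac <- (xs[i] - level) / (xs[i] - xs[i + 1])
  (idx[i] - 1 + frac) / rate
}
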