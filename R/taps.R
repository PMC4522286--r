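# Tap event detection: discrete supra-threshold force events per channel.

#' Detect tap events in a force recording
#'
#' Per channel, an event begins at an upward crossing of the force threshold,
#' peaks at the local maximum and ends at the downward crossing; events whose
#' gap is shorter than the refractory interval are merged. Onset times are
#' linearly interpolated between samples.
#'
#' @param rec An `ffm_recording` at the analysis rate (100 Hz).
#' @param threshold Detection threshold in N (events must exceed it).
#' @param refractory Merge interval in seconds.
#' @return Data frame of tap events (`finger`, `onset_time`, `peak_time`,
#'   `amplitude`), sorted by peak time; zero rows if none.
#' @export
detect_taps <- function(rec, threshold = 0.5, refractory = 0.1) {
  stopifnot(inherits(rec, "ffm_recording"))
  rate <- rec$sample_rate
  out <- list()
  for (ch in FFM_FINGERS) {
    x <- rec$samples[, ch]
    above <- x > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])

    # merge runs separated by less than the refractory interval
    if (nrow(runs) > 1) {
      keep <- list(runs[1, ])
      for (j in 2:nrow(runs)) {
        prev <- keep[[length(keep)]]
        if ((runs[j, 1] - prev[2]) / rate < refractory) {
          keep[[length(keep)]] <- c(prev[1], runs[j, 2])
        } else {
          keep[[length(keep) + 1]] <- runs[j, ]
        }
      }
      runs <- do.call(rbind, keep)
    }

    for (j in seq_len(nrow(runs))) {
      i0 <- runs[j, 1]
      i1 <- runs[j, 2]
      pk <- i0 + which.max(x[i0:i1]) - 1L
      onset <- if (i0 > 1) {
        frac <- (threshold - x[i0 - 1]) / (x[i0] - x[i0 - 1])
        (i0 - 2 + frac) / rate
      } else {
        0
      }
      out[[length(out) + 1]] <- data.frame(
        finger = ch, onset_time = onset, peak_time = (pk - 1) / rate,
        amplitude = x[pk], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(finger = character(0), onset_time = numeric(0),
                      peak_time = numeric(0), amplitude = numeric(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$peak_time), , drop = FALSE]
  rownames(res) <- NULL
  res
}
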