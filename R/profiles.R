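# Individual dexterity profiles: the six discriminatory measures, control
# norms (mean + 2 SD), pathology flags, and the thin statistical surface
# (two-sample comparison, rank / linear correlation).

FFM_PROFILE_MEASURES <- c("tracking_error", "release_duration",
                          "one_minus_slope", "overflow_taps_1hz",
                          "omission_rate", "ueft_one_finger")

#' Compute a subject's dexterity profile
#'
#' The six component measures, each oriented so that larger values indicate
#' worse performance: index-finger tracking error (mean RMSE over trials,
#' ramp and hold pooled, both force levels), mean release duration (1 N and
#' 2 N trials pooled), one minus the index-finger tapping-rate slope across
#' 1-3 Hz, number of overflow taps in the 1 Hz conditions, omission rate
#' across one- and two-finger multi-tap trials, and unwanted
#' extra-finger-taps in one-finger trials. Missing tasks yield missing (NA)
#' measures.
#'
#' @param tracking An `ffm_tracking_result` or NULL.
#' @param single An `ffm_single_result` or NULL.
#' @param multi An `ffm_multi_result` or NULL.
#' @param subject_id,group Optional identifiers carried through.
#' @return An `ffm_profile`: list with `measures` (named numeric, NA where
#'   unavailable), empty `flags`, and the identifiers.
#' @export
compute_profile <- function(tracking = NULL, single = NULL, multi = NULL,
                            subject_id = NA_character_, group = NA_character_) {
  m <- stats::setNames(rep(NA_real_, length(FFM_PROFILE_MEASURES)),
                       FFM_PROFILE_MEASURES)
  if (!is.null(tracking)) {
    tr <- tracking$trials
    err <- c(tr$rmse_ramp, tr$rmse_hold)
    m["tracking_error"] <- if (any(!is.na(err))) mean(err, na.rm = TRUE) else NA_real_
    rd <- tr$release_duration
    m["release_duration"] <- if (any(!is.na(rd))) mean(rd, na.rm = TRUE) else NA_real_
  }
  if (!is.null(single)) {
    sl <- single$slopes$slope[single$slopes$finger == "index"]
    if (length(sl) == 1 && is.finite(sl)) m["one_minus_slope"] <- 1 - sl
    m["overflow_taps_1hz"] <- single$overflow_1hz
  }
  if (!is.null(multi)) {
    m["omission_rate"] <- multi$summary$omission_rate
    m["ueft_one_finger"] <- multi$summary$ueft_one_finger
  }
  structure(list(subject_id = subject_id, group = group, measures = m,
                 flags = stats::setNames(rep(NA, length(m)), names(m))),
            class = "ffm_profile")
}

#' @export
print.ffm_profile <- function(x, ...) {
  cat("<ffm_profile>", if (!is.na(x$subject_id)) x$subject_id else "", "\n")
  df <- data.frame(measure = names(x$measures),
                   value = unname(x$measures),
                   pathological = unname(x$flags))
  print(df, digits = 3, row.names = FALSE)
  invisible(x)
}

profiles_to_matrix <- function(profiles) {
  if (inherits(profiles, "ffm_profile")) profiles <- list(profiles)
  t(vapply(profiles, function(p) p$measures,
           numeric(length(FFM_PROFILE_MEASURES))))
}

#' Control norms for the profile measures
#'
#' Per-measure mean, sample SD and pathology threshold (mean + 2 SD)
#' computed from control profiles; a measure with fewer than two defined
#' values is marked unavailable (NA).
#'
#' @param control_profiles List of `ffm_profile` objects.
#' @return An `ffm_norms`: data frame with `measure`, `mean`, `sd`,
#'   `threshold`, `n`, plus attribute `n_controls`.
#' @export
compute_norms <- function(control_profiles) {
  if (length(control_profiles) == 0) stop("no control profiles supplied")
  mat <- profiles_to_matrix(control_profiles)
  rows <- lapply(FFM_PROFILE_MEASURES, function(me) {
    v <- mat[, me]
    v <- v[!is.na(v)]
    if (length(v) < 2) {
      data.frame(measure = me, mean = NA_real_, sd = NA_real_,
                 threshold = NA_real_, n = length(v), stringsAsFactors = FALSE)
    } else {
      data.frame(measure = me, mean = mean(v), sd = stats::sd(v),
                 threshold = mean(v) + 2 * stats::sd(v), n = length(v),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "n_controls") <- length(control_profiles)
  class(out) <- c("ffm_norms", "data.frame")
  out
}

#' Flag pathological profile measures against control norms
#'
#' A measure is pathological when it strictly exceeds the control
#' mean + 2 SD threshold (a value exactly at the threshold is not flagged).
#' Flags are NA where the measure or its norm is unavailable.
#'
#' @param profile An `ffm_profile`.
#' @param norms An `ffm_norms` from [compute_norms()].
#' @return The profile with its `flags` filled in.
#' @export
flag_pathology <- function(profile, norms) {
  stopifnot(inherits(profile, "ffm_profile"), inherits(norms, "ffm_norms"))
  thr <- stats::setNames(norms$threshold, norms$measure)
  profile$flags <- profile$measures > thr[names(profile$measures)]
  profile
}

#' Clinical pathology flags
#'
#' The Moberg Pick-Up time of the affected hand is flagged pathological when
#' it exceeds 18 seconds; other clinical scores are reported as given.
#'
#' @param clinical Named list with (optionally) `moberg_s` as
#'   `c(affected, nonaffected)` seconds, `arat_total`, `grip_force_kg`,
#'   `monofilament_g`.
#' @return List with `moberg_pathological` (logical or NA) and the raw
#'   scores.
#' @export
flag_clinical <- function(clinical) {
  moberg <- clinical$moberg_s
  flag <- if (is.null(moberg) || is.na(moberg[1])) NA else moberg[1] > 18
  list(moberg_pathological = flag, clinical = clinical)
}

#' Correlate a performance measure with a clinical score
#'
#' Pairs with missing values are dropped; at least three complete pairs are
#' required. Spearman's rank correlation serves measure-vs-clinical tests,
#' Pearson's the relations between performance measures (for which the
#' squared coefficient is also reported).
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"spearman"` or `"pearson"`.
#' @return List with `coefficient`, `r_squared`, `p_value`, `n`, `method`;
#'   coefficient is NA (with a note) when either vector has zero variance.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("correlate: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(coefficient = NA_real_, r_squared = NA_real_,
                p_value = NA_real_, n = length(x), method = method,
                note = "zero variance"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = length(x), method = method)
}

#' Two-sample group comparison (Student's t)
#'
#' Pooled-variance two-sample t-test by default (Welch optionally), with the
#' descriptive mean +/- SD of each group. Degenerate input (zero variance in
#' both groups) yields an NA statistic flagged in `note` rather than an
#' error.
#'
#' @param patients,controls Numeric vectors (>= 2 values each).
#' @param pooled Use the pooled-variance form (default) or Welch.
#' @return List with `t_statistic`, `p_value`, `df`, per-group `mean` and
#'   `sd`, and optionally `note`.
#' @export
group_compare <- function(patients, controls, pooled = TRUE) {
  patients <- patients[is.finite(patients)]
  controls <- controls[is.finite(controls)]
  if (length(patients) < 2 || length(controls) < 2) {
    stop("group_compare: need at least 2 values per group")
  }
  desc <- list(patients = c(mean = mean(patients), sd = stats::sd(patients)),
               controls = c(mean = mean(controls), sd = stats::sd(controls)))
  tt <- tryCatch(stats::t.test(patients, controls, var.equal = pooled),
                 error = function(e) NULL)
  if (is.null(tt)) {
    return(c(list(t_statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                  note = "zero pooled variance"), desc))
  }
  c(list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter)), desc)
}
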