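# Synthetic cohorts: per-subject parameter draws around the group presets,
# with clinical scores tied to the impairment severity so correlation
# analyses have signal, and a convenience wrapper running a subject's
# recordings through the full analysis into a dexterity profile.

sim_clinical <- function(severity) {
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  arat <- round(clamp(57 - 28 * severity + stats::rnorm(1, 0, 2), 0, 57))
  moberg_aff <- clamp(8 + 35 * severity + stats::rnorm(1, 0, 1.5), 3, 120)
  moberg_non <- clamp(8 + stats::rnorm(1, 0, 1), 3, 120)
  grip_aff <- clamp(40 * (1 - 0.6 * severity) + stats::rnorm(1, 0, 3), 1, 80)
  grip_non <- clamp(40 + stats::rnorm(1, 0, 3), 1, 80)
  mono_aff <- clamp(0.07 + 0.5 * severity + stats::rnorm(1, 0, 0.05), 0.07, 2)
  list(arat_total = arat,
       grip_force_kg = c(affected = grip_aff, nonaffected = grip_non),
       moberg_s = c(affected = moberg_aff, nonaffected = moberg_non),
       monofilament_g = c(affected = mono_aff, nonaffected = 0.07))
}

#' Generate a synthetic cohort of control-like and paretic-like subjects
#'
#' Each subject draws an impairment severity (controls near 0, patients
#' higher), simulator parameters blended between the two presets at that
#' severity, task recordings with ground truth, and clinical scores
#' (synthetic ARAT, Moberg times, grip force) constructed to co-vary with
#' severity. Fully reproducible under `seed`.
#'
#' @param n_controls,n_patients Group sizes (>= 0).
#' @param seed Integer seed.
#' @param tasks Tasks to simulate per subject; default the three tasks
#'   feeding the dexterity profile.
#' @param protocols Named list of protocols per task; defaults built with
#'   the standard parameters.
#' @param control_severity,patient_severity Severity ranges (uniform draws).
#' @return An `ffm_cohort`: list with `subjects` (each carrying subject_id,
#'   group, severity, params, clinical, recordings, truths) and `protocols`.
#' @export
make_cohort <- function(n_controls, n_patients, seed = 1L,
                        tasks = c("tracking", "single_tap", "multi_tap"),
                        protocols = NULL,
                        control_severity = c(0, 0.15),
                        patient_severity = c(0.3, 1)) {
  check_positive(n_controls, "n_controls", strict = FALSE)
  check_positive(n_patients, "n_patients", strict = FALSE)
  tasks <- match.arg(tasks, c("tracking", "single_tap", "multi_tap",
                              "sequential"), several.ok = TRUE)
  if (is.null(protocols)) {
    protocols <- list(tracking = build_tracking_protocol(),
                      single_tap = build_single_tap_protocol(),
                      multi_tap = build_multi_tap_protocol(seed = seed),
                      sequential = build_sequence_protocol())
  }
  groups <- rep(c("control", "patient"), c(n_controls, n_patients))
  subjects <- with_seed(seed, lapply(seq_along(groups), function(i) {
    grp <- groups[i]
    rng <- if (grp == "control") control_severity else patient_severity
    sev <- stats::runif(1, rng[1], rng[2])
    sub_seed <- sample.int(.Machine$integer.max - 8L, 1)
    params <- blend_params(sev, seed = sub_seed)
    clinical <- sim_clinical(sev)
    recordings <- list()
    truths <- list()
    for (tk in tasks) {
      params_tk <- params
      params_tk$seed <- sub_seed + match(tk, c("tracking", "single_tap",
                                               "multi_tap", "sequential"))
      sim <- if (tk == "tracking") {
        simulate_tracking(protocols[[tk]], params_tk, finger = "index")
      } else {
        simulate_tapping(protocols[[tk]], params_tk)
      }
      sim$recording$meta$subject_id <- sprintf("%s%02d", toupper(substr(grp, 1, 1)), i)
      sim$recording$meta$group <- grp
      recordings[[tk]] <- sim$recording
      truths[[tk]] <- sim$truth
    }
    list(subject_id = sprintf("%s%02d", toupper(substr(grp, 1, 1)), i),
         group = grp, severity = sev, params = params, clinical = clinical,
         recordings = recordings, truths = truths)
  }))
  structure(list(subjects = subjects, protocols = protocols,
                 seed = as.integer(seed)),
            class = "ffm_cohort")
}

#' @export
print.ffm_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, "", "group")
  cat("<ffm_cohort>", sum(grp == "control"), "controls,",
      sum(grp == "patient"), "patients (seed", x$seed, ")\n")
  invisible(x)
}

#' Analyze a subject's recordings into a dexterity profile
#'
#' Runs whichever of the tracking, single-tap and multi-tap recordings are
#' present through their analyses and assembles the six-measure profile.
#'
#' @param recordings Named list of `ffm_recording`s (names among `tracking`,
#'   `single_tap`, `multi_tap`).
#' @param protocols Named list of the matching protocols.
#' @param subject_id,group Carried into the profile.
#' @return An `ffm_profile`.
#' @export
analyze_subject <- function(recordings, protocols,
                            subject_id = NA_character_, group = NA_character_) {
  tr <- if (!is.null(recordings$tracking)) {
    analyze_tracking(recordings$tracking, protocols$tracking)
  }
  st <- if (!is.null(recordings$single_tap)) {
    analyze_single_tap(recordings$single_tap, protocols$single_tap)
  }
  mt <- if (!is.null(recordings$multi_tap)) {
    analyze_multi_tap(recordings$multi_tap, protocols$multi_tap)
  }
  compute_profile(tracking = tr, single = st, multi = mt,
                  subject_id = subject_id, group = group)
}

#' Profile every subject of a cohort
#'
#' @param cohort An `ffm_cohort`.
#' @return List of `ffm_profile`s, one per subject.
#' @export
cohort_profiles <- function(cohort) {
  stopifnot(inherits(cohort, "ffm_cohort"))
  lapply(cohort$subjects, function(s) {
    analyze_subject(s$recordings, cohort$protocols,
                    subject_id = s$subject_id, group = s$group)
  })
}
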