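# Generative model parameters and the two study presets.

#' Simulator parameters
#'
#' Parameters of the seedable generative model of four-finger force traces.
#' Forces are in newtons, times in seconds, rates in Hz.
#'
#' @param tracking_noise_sd SD of white force noise in the tracking task.
#' @param tracking_lag Visuo-motor delay of the tracking response.
#' @param release_tau Exponential time constant of force release after the
#'   hold phase (0 = instantaneous release).
#' @param baseline_offset Residual force between trials/taps (impaired
#'   relaxation), added to all channels.
#' @param tap_amplitude Mean peak force of a tap pulse (the instructed tap
#'   force is 2 N).
#' @param tap_amplitude_sd Between-tap SD of the peak force.
#' @param tap_width Full duration of the raised-cosine tap pulse.
#' @param tap_jitter_sd SD of tap timing jitter around the cue.
#' @param reaction_s Mean cue-to-peak latency of a tap.
#' @param max_rate Tapping-rate ceiling: intended taps closer than
#'   `1/max_rate` to the previous produced tap on the same finger are dropped.
#' @param enslaving 4x4 coupling matrix, `enslaving[lead, d]` scaling the
#'   pulse transmitted from a tapping lead finger to finger `d`; unit
#'   diagonal, entries in `[0, 1]`.
#' @param omission_prob Probability that a cued target finger produces no tap.
#' @param extra_tap_prob Probability per cue of one spontaneous tap on a
#'   non-target finger.
#' @param tap_noise_sd SD of white sensor noise in the tapping tasks.
#' @param detection_threshold Force threshold linking the generator's ground
#'   truth to tap detection: a pulse is recorded as a ground-truth tap event
#'   iff its sampled trace peak exceeds this value (0.5 N, the detection
#'   threshold used by the analyzer).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return An object of class `ffm_sim_params`.
#' @seealso [ffm_preset()] for the control-like and paretic-like presets.
#' @export
sim_params <- function(tracking_noise_sd = 0.04, tracking_lag = 0.12,
                       release_tau = 0.05, baseline_offset = 0,
                       tap_amplitude = 2, tap_amplitude_sd = 0.25,
                       tap_width = 0.15, tap_jitter_sd = 0.03,
                       reaction_s = 0.15, max_rate = 5,
                       enslaving = diag(4), omission_prob = 0,
                       extra_tap_prob = 0, tap_noise_sd = 0.02,
                       detection_threshold = 0.5, seed = NULL) {
  check_positive(tracking_noise_sd, "tracking_noise_sd", strict = FALSE)
  check_positive(tracking_lag, "tracking_lag", strict = FALSE)
  check_positive(release_tau, "release_tau", strict = FALSE)
  check_positive(tap_amplitude, "tap_amplitude")
  check_positive(tap_amplitude_sd, "tap_amplitude_sd", strict = FALSE)
  check_positive(tap_width, "tap_width")
  check_positive(tap_jitter_sd, "tap_jitter_sd", strict = FALSE)
  check_positive(reaction_s, "reaction_s", strict = FALSE)
  check_positive(max_rate, "max_rate")
  check_positive(tap_noise_sd, "tap_noise_sd", strict = FALSE)
  check_probability(omission_prob, "omission_prob")
  check_probability(extra_tap_prob, "extra_tap_prob")
  enslaving <- as.matrix(enslaving)
  if (!all(dim(enslaving) == c(4, 4)) || any(enslaving < 0) ||
      any(enslaving > 1) || any(abs(diag(enslaving) - 1) > 1e-12)) {
    stop("invalid parameter: enslaving must be 4x4 with entries in [0,1] and unit diagonal")
  }
  dimnames(enslaving) <- list(FFM_FINGERS, FFM_FINGERS)
  structure(list(tracking_noise_sd = tracking_noise_sd,
                 tracking_lag = tracking_lag, release_tau = release_tau,
                 baseline_offset = baseline_offset,
                 tap_amplitude = tap_amplitude,
                 tap_amplitude_sd = tap_amplitude_sd, tap_width = tap_width,
                 tap_jitter_sd = tap_jitter_sd, reaction_s = reaction_s,
                 max_rate = max_rate, enslaving = enslaving,
                 omission_prob = omission_prob,
                 extra_tap_prob = extra_tap_prob, tap_noise_sd = tap_noise_sd,
                 detection_threshold = detection_threshold,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ffm_sim_params")
}

#' @export
print.ffm_sim_params <- function(x, ...) {
  cat("<ffm_sim_params>\n")
  cat("  tracking: noise", x$tracking_noise_sd, "N, lag", x$tracking_lag,
      "s, release tau", x$release_tau, "s, baseline", x$baseline_offset, "N\n")
  cat("  tapping: amp", x$tap_amplitude, "N, width", x$tap_width,
      "s, jitter", x$tap_jitter_sd, "s, max rate", x$max_rate, "Hz\n")
  cat("  omission", x$omission_prob, " extra", x$extra_tap_prob,
      " neighbor enslaving", x$enslaving[1, 2], "\n")
  invisible(x)
}

# Symmetric distance-decaying enslaving matrix: coupling depends only on the
# anatomical distance between digits (d1 = neighbors, d3 = index<->little).
enslaving_matrix <- function(d1, d2, d3) {
  w <- c(1, d1, d2, d3)
  E <- outer(1:4, 1:4, function(i, j) w[abs(i - j) + 1])
  dimnames(E) <- list(FFM_FINGERS, FFM_FINGERS)
  E
}

#' Simulator presets for the two study groups
#'
#' `control_like`: low noise, fast release, near-zero baseline, rate ceiling
#' well above 3 Hz, near-diagonal enslaving, rare omissions/extras.
#' `paretic_like`: elevated noise, slow release (time constant chosen so the
#' 75-to-25% release takes about half a second), positive residual baseline,
#' rate ceiling below 3 Hz, enslaving decaying with anatomical distance
#' (neighbors strongest), and substantial omission and extra-tap rates.
#' These values are the package's own plausible settings, not estimates of
#' any cohort.
#'
#' @param group `"control_like"` or `"paretic_like"`.
#' @param seed Optional seed stored in the returned parameters.
#' @return An `ffm_sim_params`.
#' @export
ffm_preset <- function(group = c("control_like", "paretic_like"), seed = NULL) {
  group <- match.arg(group)
  if (group == "control_like") {
    sim_params(tracking_noise_sd = 0.04, tracking_lag = 0.12,
               release_tau = 0.05, baseline_offset = 0.02,
               tap_amplitude = 2, tap_amplitude_sd = 0.25, tap_width = 0.15,
               tap_jitter_sd = 0.03, reaction_s = 0.15, max_rate = 5,
               enslaving = enslaving_matrix(0.05, 0.02, 0.01),
               omission_prob = 0.01, extra_tap_prob = 0.01,
               tap_noise_sd = 0.02, seed = seed)
  } else {
    sim_params(tracking_noise_sd = 0.12, tracking_lag = 0.25,
               release_tau = 0.45, baseline_offset = 0.28,
               tap_amplitude = 2, tap_amplitude_sd = 0.35, tap_width = 0.18,
               tap_jitter_sd = 0.08, reaction_s = 0.2, max_rate = 2.4,
               enslaving = enslaving_matrix(0.45, 0.12, 0.03),
               omission_prob = 0.15, extra_tap_prob = 0.2,
               tap_noise_sd = 0.04, seed = seed)
  }
}

# Linear blend between the two presets at impairment severity s in [0, 1]
# (0 = control-like, 1 = paretic-like).
blend_params <- function(severity, seed = NULL) {
  a <- ffm_preset("control_like")
  b <- ffm_preset("paretic_like")
  lerp <- function(u, v) (1 - severity) * u + severity * v
  sim_params(tracking_noise_sd = lerp(a$tracking_noise_sd, b$tracking_noise_sd),
             tracking_lag = lerp(a$tracking_lag, b$tracking_lag),
             release_tau = lerp(a$release_tau, b$release_tau),
             baseline_offset = lerp(a$baseline_offset, b$baseline_offset),
             tap_amplitude = lerp(a$tap_amplitude, b$tap_amplitude),
             tap_amplitude_sd = lerp(a$tap_amplitude_sd, b$tap_amplitude_sd),
             tap_width = lerp(a$tap_width, b$tap_width),
             tap_jitter_sd = lerp(a$tap_jitter_sd, b$tap_jitter_sd),
             reaction_s = lerp(a$reaction_s, b$reaction_s),
             max_rate = lerp(a$max_rate, b$max_rate),
             enslaving = lerp(a$enslaving, b$enslaving),
             omission_prob = lerp(a$omission_prob, b$omission_prob),
             extra_tap_prob = lerp(a$extra_tap_prob, b$extra_tap_prob),
             tap_noise_sd = lerp(a$tap_noise_sd, b$tap_noise_sd),
             seed = seed)
}
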