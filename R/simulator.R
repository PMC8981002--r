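#' Subject profile
#'
#' Body morphology and watch placement for one participant. Height and
#' weight bounds cover the adult range; the study cohort spanned
#' 153-184 cm and 47-110 kg.
#'
#' @param height_cm height in cm, within \[100, 230\].
#' @param weight_kg weight in kg, within \[30, 200\].
#' @param watch_side `"left"` or `"right"` wrist.
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(height_cm = 170, weight_kg = 70,
                            watch_side = c("left", "right")) {
  watch_side <- match.arg(watch_side)
  if (!is.finite(height_cm) || height_cm < 100 || height_cm > 230)
    stop("height_cm must be within [100, 230]")
  if (!is.finite(weight_kg) || weight_kg < 30 || weight_kg > 200)
    stop("weight_kg must be within [30, 200]")
  structure(list(height_cm = height_cm, weight_kg = weight_kg,
                 watch_side = watch_side), class = "subject_profile")
}

#' Simulator parameters
#'
#' Shape and noise parameters of the synthetic wrist-accelerometer signal.
#' A fall signature is a free-fall dip (magnitude dropping to about
#' `freefall_depth` for `freefall_dur` s), a half-sine impact spike
#' (peaking around `impact_peak` for `impact_dur` s) and a rest plateau at
#' 1 g; walking is a sinusoid of amplitude `walk_amp` at `walk_freq` Hz
#' around 1 g. When a side fall lands on the wrist opposite the watch, the
#' dip excursion and impact peak are attenuated by `contralateral_atten`
#' (the watch arm swings with, rather than under, the body). A near fall
#' is the fall signature scaled by `near_fall_scale` with the rest plateau
#' replaced by `recovery_dur` s of recovery steps of amplitude
#' `recovery_amp`, chosen so the post-impact rest fraction lands in the
#' detector's near-fall margin band.
#'
#' @param rate sampling rate, Hz.
#' @param freefall_depth mean free-fall dip magnitude, g.
#' @param freefall_dur free-fall duration, s.
#' @param impact_peak mean impact peak, g.
#' @param impact_dur impact spike duration, s.
#' @param rest_dur post-impact rest duration, s.
#' @param rest_noise_sd rest plateau noise sd, g.
#' @param walk_amp walking oscillation amplitude, g.
#' @param walk_freq walking cadence, Hz.
#' @param walk_noise_sd walking noise sd, g.
#' @param contralateral_atten multiplicative attenuation of dip excursion
#'   and impact peak for side falls opposite the watch wrist, in (0, 1].
#' @param near_fall_scale factor mapping a fall signature to a near-fall
#'   signature, in (0, 1).
#' @param device_scale per-device amplitude multiplier on the impact peak
#'   and dip excursion (models sensor/operating-system differences).
#' @param impact_jitter_sd per-fall sd of the impact peak, g.
#' @param depth_jitter_sd per-fall sd of the free-fall depth, g.
#' @param recovery_amp recovery-step oscillation amplitude, g.
#' @param recovery_dur recovery-step duration after a near fall, s.
#' @param seed optional default seed used by the `simulate_*` functions.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(rate = 100, freefall_depth = 0.3, freefall_dur = 0.3,
                       impact_peak = 3.2, impact_dur = 0.05, rest_dur = 3.0,
                       rest_noise_sd = 0.02, walk_amp = 0.3, walk_freq = 2.0,
                       walk_noise_sd = 0.05, contralateral_atten = 0.75,
                       near_fall_scale = 0.85, device_scale = 1.0,
                       impact_jitter_sd = 0.25, depth_jitter_sd = 0.05,
                       recovery_amp = 0.26, recovery_dur = 2.0,
                       seed = NULL) {
  p <- list(rate = rate, freefall_depth = freefall_depth,
            freefall_dur = freefall_dur, impact_peak = impact_peak,
            impact_dur = impact_dur, rest_dur = rest_dur,
            rest_noise_sd = rest_noise_sd, walk_amp = walk_amp,
            walk_freq = walk_freq, walk_noise_sd = walk_noise_sd,
            contralateral_atten = contralateral_atten,
            near_fall_scale = near_fall_scale, device_scale = device_scale,
            impact_jitter_sd = impact_jitter_sd,
            depth_jitter_sd = depth_jitter_sd, recovery_amp = recovery_amp,
            recovery_dur = recovery_dur, seed = seed)
  stopifnot(p$rate > 0, p$freefall_depth > 0, p$freefall_dur > 0,
            p$impact_peak > 0, p$impact_dur > 0, p$rest_dur > 0,
            p$walk_amp > 0, p$walk_freq > 0,
            p$contralateral_atten > 0, p$contralateral_atten <= 1,
            p$near_fall_scale > 0, p$near_fall_scale < 1,
            p$device_scale > 0)
  structure(p, class = "sim_params")
}

#' Induced-fall session protocol
#'
#' The study protocol: per session, `rounds` rounds of four directed falls
#' (forward, right, left, backward — two per direction when `rounds = 2`),
#' separated by free-walking intervals, optionally preceded by excluded
#' test falls (used for threshold calibration, not analysis) and followed
#' by step-recovery near falls.
#'
#' @param rounds number of rounds of four directed falls.
#' @param inter_fall_walk_s seconds of free walking between events.
#' @param near_falls number of near falls appended to the session.
#' @param test_falls number of calibration test falls before round one
#'   (excluded from the reference log; their intervals are attached as the
#'   `"calibration"` attribute of the event log).
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(rounds = 2, inter_fall_walk_s = 20,
                          near_falls = 0, test_falls = 0) {
  stopifnot(rounds >= 0, inter_fall_walk_s >= 0, near_falls >= 0,
            test_falls >= 0)
  structure(list(rounds = as.integer(rounds),
                 directions = c("forward", "right", "left", "backward"),
                 inter_fall_walk_s = inter_fall_walk_s,
                 near_falls = as.integer(near_falls),
                 test_falls = as.integer(test_falls)),
            class = "protocol_spec")
}

# magnitude profile -> tri-axial samples along a slowly wobbling unit
# direction biased toward the given fall direction; preserves |a| exactly
compose_axes <- function(mag, direction, rate) {
  dir_vec <- switch(direction,
                    forward = c(1, 0, 0), backward = c(-1, 0, 0),
                    left = c(0, 1, 0), right = c(0, -1, 0),
                    none = c(0, 0, 0))
  n <- length(mag)
  t <- (seq_len(n) - 1L) / rate
  u <- cbind(0.5 * dir_vec[1L] + 0.1 * sin(2 * pi * 0.7 * t),
             0.5 * dir_vec[2L] + 0.1 * cos(2 * pi * 0.9 * t),
             rep(1, n))
  u <- u / sqrt(rowSums(u^2))
  u * mag
}

walk_magnitude <- function(dur, params, phase = stats::runif(1, 0, 2 * pi)) {
  n <- max(1L, as.integer(round(dur * params$rate)))
  t <- (seq_len(n) - 1L) / params$rate
  1 + params$walk_amp * sin(2 * pi * params$walk_freq * t + phase) +
    stats::rnorm(n, 0, params$walk_noise_sd)
}

# Shared core of the fall / near-fall signatures: returns the magnitude
# profile and the impact-onset offset in seconds.
fall_magnitude <- function(profile, direction, params, scale = 1) {
  rate <- params$rate
  atten <- if (direction %in% c("left", "right") &&
               direction != profile$watch_side)
    params$contralateral_atten else 1
  pad <- walk_magnitude(1.0, params)
  depth <- params$freefall_depth + stats::rnorm(1, 0, params$depth_jitter_sd)
  depth <- min(max(depth, 0.05), 0.55)
  excursion <- (1 - depth) * atten * scale * params$device_scale
  n1 <- as.integer(round(params$freefall_dur * rate))
  dip <- 1 - excursion + stats::rnorm(n1, 0, 0.02)
  peak <- (params$impact_peak + stats::rnorm(1, 0, params$impact_jitter_sd)) *
    atten * scale * params$device_scale
  peak <- max(peak, 1.1)
  n2 <- max(3L, as.integer(round(params$impact_dur * rate)))
  spike <- pmax(1, peak * sin(pi * seq_len(n2) / (n2 + 1L)))
  list(mag = c(pad, dip, spike), t_impact = (length(pad) + n1) / rate)
}

#' Simulate one directed-fall signature
#'
#' Generates a trace segment containing one induced fall: one second of
#' pre-fall walking, the free-fall dip, the impact spike and the rest
#' plateau, with seeded jitter on depth and peak. Side falls opposite the
#' watch wrist are attenuated by `contralateral_atten`.
#'
#' @param profile a [subject_profile()].
#' @param direction `"forward"`, `"backward"`, `"left"` or `"right"`.
#' @param params a [sim_params()].
#' @return An [accel_trace()] segment with attribute `"t_impact"`, the
#'   impact onset in seconds from segment start.
#' @export
simulate_fall_signature <- function(profile, direction,
                                    params = sim_params()) {
  fm <- fall_magnitude(profile, direction, params)
  nr <- as.integer(round(params$rest_dur * params$rate))
  mag <- c(fm$mag, 1 + stats::rnorm(nr, 0, params$rest_noise_sd))
  tr <- accel_trace(compose_axes(mag, direction, params$rate),
                    rate = params$rate)
  attr(tr, "t_impact") <- fm$t_impact
  tr
}

#' Simulate one near-fall signature
#'
#' A fall signature scaled by `near_fall_scale` whose rest plateau is
#' replaced by recovery steps (the participant steps in the push direction
#' instead of coming to rest). By construction under the default detector
#' thresholds the post-impact rest fraction lands in the near-fall margin
#' band, so the segment classifies as a near fall, not a fall.
#'
#' @inheritParams simulate_fall_signature
#' @return An [accel_trace()] segment with attribute `"t_impact"`.
#' @export
simulate_near_fall_signature <- function(profile, direction,
                                         params = sim_params()) {
  fm <- fall_magnitude(profile, direction, params,
                       scale = params$near_fall_scale)
  n3 <- as.integer(round(params$recovery_dur * params$rate))
  t <- (seq_len(n3) - 1L) / params$rate
  recovery <- 1 + params$recovery_amp *
    sin(2 * pi * params$walk_freq * t + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n3, 0, 0.02)
  mag <- c(fm$mag, recovery)
  tr <- accel_trace(compose_axes(mag, direction, params$rate),
                    rate = params$rate)
  attr(tr, "t_impact") <- fm$t_impact
  tr
}

#' Simulate one induced-fall session
#'
#' Concatenates free-walking intervals with fall and near-fall signatures
#' following the protocol (per round: forward, right, left, backward) and
#' returns the trace together with the ground-truth reference log: one
#' `fall` event per induced fall, one `near_fall` per requested near fall
#' and one `nonfall_segment` per walking interval. Calibration test falls,
#' if requested, precede round one and are excluded from the log; their
#' intervals are attached as the `"calibration"` attribute.
#'
#' @param profile a [subject_profile()].
#' @param protocol a [protocol_spec()].
#' @param params a [sim_params()].
#' @param seed integer seed; defaults to `params$seed`. `NULL` leaves the
#'   RNG stream untouched.
#' @return A list with elements `trace` ([accel_trace()]) and `events`
#'   (`event_log`).
#' @export
simulate_session <- function(profile, protocol = protocol_spec(),
                             params = sim_params(), seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  rate <- params$rate
  segs <- list()
  kind <- dir <- character()
  t_start <- t_end <- numeric()
  calib <- NULL
  t_cur <- 0
  add_walk <- function(dur) {
    mag <- walk_magnitude(dur, params)
    segs[[length(segs) + 1L]] <<- compose_axes(mag, "none", rate)
    kind <<- c(kind, "nonfall_segment"); dir <<- c(dir, "none")
    t_start <<- c(t_start, t_cur); t_end <<- c(t_end, t_cur + dur)
    t_cur <<- t_cur + dur
  }
  add_signature <- function(what, direction, log_it = TRUE) {
    seg <- if (what == "fall")
      simulate_fall_signature(profile, direction, params)
    else simulate_near_fall_signature(profile, direction, params)
    dur <- length(seg) / rate
    ti <- t_cur + attr(seg, "t_impact")
    if (log_it) {
      kind <<- c(kind, what); dir <<- c(dir, direction)
      t_start <<- c(t_start, ti - 0.5); t_end <<- c(t_end, ti + 1.5)
    } else {
      calib <<- rbind(calib, data.frame(t_start = ti - 0.5, t_end = ti + 1.5))
    }
    segs[[length(segs) + 1L]] <<- seg$data
    t_cur <<- t_cur + dur
  }
  add_walk(protocol$inter_fall_walk_s)
  if (protocol$test_falls > 0)
    for (j in seq_len(protocol$test_falls)) {
      add_signature("fall", "forward", log_it = FALSE)
      add_walk(protocol$inter_fall_walk_s)
    }
  if (protocol$rounds > 0)
    for (r in seq_len(protocol$rounds))
      for (d in protocol$directions) {
        add_signature("fall", d)
        add_walk(protocol$inter_fall_walk_s)
      }
  if (protocol$near_falls > 0)
    for (j in seq_len(protocol$near_falls)) {
      add_signature("near_fall",
                    protocol$directions[(j - 1L) %% 4L + 1L])
      add_walk(protocol$inter_fall_walk_s)
    }
  trace <- accel_trace(do.call(rbind, segs), rate = rate)
  events <- reference_events(kind, dir, t_start, t_end)
  attr(events, "calibration") <- calib
  list(trace = trace, events = events)
}

#' Simulate a multi-subject induced-fall study
#'
#' Draws subject profiles (height uniform in 153-184 cm, weight uniform in
#' 47-110 kg, watch side alternating left/right, device model cycling
#' A/B/C) and simulates one session per subject. Deterministic given the
#' seed.
#'
#' @param n_subjects number of participants.
#' @param protocol a [protocol_spec()].
#' @param params a [sim_params()].
#' @param seed integer seed for the whole study.
#' @param device_scales named amplitude multipliers per device model.
#' @return A list with one element per subject: `subject_id`, `profile`,
#'   `device`, `trace`, `events`.
#' @export
simulate_study <- function(n_subjects = 22, protocol = protocol_spec(),
                           params = sim_params(), seed = 1,
                           device_scales = c(A = 1, B = 1, C = 1)) {
  if (!is.null(seed)) set.seed(seed)
  if (n_subjects < 1) return(list())
  devices <- names(device_scales)
  lapply(seq_len(n_subjects), function(s) {
    prof <- subject_profile(height_cm = stats::runif(1, 153, 184),
                            weight_kg = stats::runif(1, 47, 110),
                            watch_side = if (s %% 2L) "left" else "right")
    dev <- devices[(s - 1L) %% length(devices) + 1L]
    p <- params
    p$device_scale <- params$device_scale * unname(device_scales[dev])
    sess <- simulate_session(prof, protocol, p, seed = NULL)
    c(list(subject_id = s, profile = prof, device = dev), sess)
  })
}
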