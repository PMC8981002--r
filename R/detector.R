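#' Detector threshold configuration
#'
#' Houses the settings of the three-phase threshold state machine. A fall
#' candidate is a free-fall dip (phase 1: magnitude below `freefall_max`,
#' i.e. well under the 1 g gravity reference, for between `t1_min` and
#' `t1_max` seconds), followed by an impact spike (phase 2: magnitude at
#' least `impact_min` within `t2_max` s of the dip ending), followed by
#' post-impact quiescence (phase 3: at least a fraction `rest_frac_min` of
#' the `t3_min`-second window after the peak inside the rest band
#' `gravity_ref +/- rest_tol`). A candidate that misses one or more full
#' thresholds but meets all of them relaxed by `near_margin` (20% by
#' default, the "close to threshold" band) is classified a near fall.
#'
#' All threshold comparisons are inclusive: a statistic exactly at a
#' threshold passes it.
#'
#' @param gravity_ref gravity reference in g (1 g = 9.8 m/s^2).
#' @param freefall_max phase-1 ceiling in g; the magnitude must drop below
#'   this (default 0.6 g).
#' @param t1_min,t1_max minimum required and maximum credited free-fall
#'   dwell, seconds (defaults 0.15 and 0.5).
#' @param impact_min phase-2 impact threshold in g (default 2.5 g).
#' @param t2_max window after phase 1 in which the impact peak must occur,
#'   seconds (default 0.2).
#' @param rest_tol half-width in g of the "almost immobile" band around
#'   `gravity_ref` (default 0.25 g).
#' @param t3_min length of the post-impact rest window, seconds (default 2).
#' @param rest_frac_min minimum fraction of rest-window samples inside the
#'   rest band (default 0.9).
#' @param near_margin fraction defining "close" to a threshold (default
#'   0.20): each threshold is relaxed by this fraction in its permissive
#'   direction (`impact_min` and `rest_frac_min` scaled by
#'   `1 - near_margin`; `freefall_max` by `1 / (1 - near_margin)`).
#' @param refractory seconds during which new candidates are suppressed
#'   after an emitted event (default 3).
#' @return A list of class `threshold_config`.
#' @seealso [detect_events()], [classify_candidate()],
#'   [calibrate_thresholds()]
#' @export
threshold_config <- function(gravity_ref = 1.0, freefall_max = 0.6,
                             t1_min = 0.15, t1_max = 0.5,
                             impact_min = 2.5, t2_max = 0.2,
                             rest_tol = 0.25, t3_min = 2.0,
                             rest_frac_min = 0.9, near_margin = 0.20,
                             refractory = 3.0) {
  cfg <- list(gravity_ref = gravity_ref, freefall_max = freefall_max,
              t1_min = t1_min, t1_max = t1_max, impact_min = impact_min,
              t2_max = t2_max, rest_tol = rest_tol, t3_min = t3_min,
              rest_frac_min = rest_frac_min, near_margin = near_margin,
              refractory = refractory)
  validate_config(cfg)
  structure(cfg, class = "threshold_config")
}

validate_config <- function(cfg) {
  num <- unlist(cfg)
  if (!all(is.finite(num))) stop("configuration error: non-finite setting")
  with(cfg, {
    if (!(0 < freefall_max && freefall_max < gravity_ref &&
          gravity_ref < impact_min))
      stop("configuration error: need 0 < freefall_max < gravity_ref < impact_min")
    if (any(c(t1_min, t1_max, t2_max, t3_min, refractory, rest_tol) <= 0))
      stop("configuration error: durations and rest_tol must be > 0")
    if (t1_max < t1_min)
      stop("configuration error: t1_max must be >= t1_min")
    if (!(near_margin > 0 && near_margin < 1))
      stop("configuration error: near_margin must be in (0, 1)")
    if (!(rest_frac_min > 0 && rest_frac_min <= 1))
      stop("configuration error: rest_frac_min must be in (0, 1]")
  })
  invisible(cfg)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (k in names(x)) cat(sprintf("  %-14s %g\n", k, x[[k]]))
  invisible(x)
}

#' Serialize / load a threshold configuration
#'
#' Flat `key=value` text format, one setting per line. [read_config()]
#' starts from `base` and overrides any key present in the file.
#'
#' @param config a [threshold_config()].
#' @param path file path.
#' @param base configuration supplying defaults for keys absent from file.
#' @return [read_config()]: a `threshold_config`; [write_config()]: the
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  writeLines(sprintf("%s=%.15g", names(config), unlist(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path, base = threshold_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- grep("=", trimws(readLines(path)), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- unclass(base)
  for (p in kv) {
    key <- trimws(p[[1L]])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- as.numeric(p[[2L]])
  }
  do.call(threshold_config, cfg)
}

#' Classify one candidate from its three phase statistics
#'
#' A candidate is a `fall` when all three phase predicates pass at full
#' thresholds; a `near_fall` when every predicate passes at the
#' margin-relaxed ("close") thresholds while at least one full-threshold
#' predicate fails; otherwise `none`. Comparisons are inclusive.
#'
#' @param phase_stats numeric vector or list with elements `p1_min`
#'   (minimum magnitude in the free-fall window, g), `p2_peak` (peak impact
#'   magnitude, g) and `p3_rest_frac` (fraction of post-impact samples in
#'   the rest band).
#' @param config a [threshold_config()].
#' @return One of `"fall"`, `"near_fall"`, `"none"`.
#' @examples
#' classify_candidate(c(0.5, 3.0, 0.95), threshold_config())  # fall
#' classify_candidate(c(0.5, 2.1, 0.95), threshold_config())  # near_fall
#' @export
classify_candidate <- function(phase_stats, config = threshold_config()) {
  validate_config(config)
  s <- unlist(phase_stats)
  if (length(s) != 3L || !all(is.finite(s)))
    stop("phase_stats must be three finite numbers")
  p1 <- s[[1L]]; p2 <- s[[2L]]; p3 <- s[[3L]]
  keep <- 1 - config$near_margin
  full <- p1 <= config$freefall_max &&
    p2 >= config$impact_min &&
    p3 >= config$rest_frac_min
  relaxed <- p1 <= config$freefall_max / keep &&
    p2 >= config$impact_min * keep &&
    p3 >= config$rest_frac_min * keep
  if (full) "fall" else if (relaxed) "near_fall" else "none"
}

# Evaluate the candidate whose phase 1 starts at sample index i.
# Returns NULL when no classifiable candidate forms there, else a list
# with the phase statistics, classification, impact index and the index
# of the last sample consumed by the phase-3 window.
candidate_at <- function(m, i, rate, config) {
  n <- length(m)
  open_level <- config$freefall_max / (1 - config$near_margin)
  cap <- floor(config$t1_max * rate)
  # phase 1: consecutive dwell below the open level, capped at t1_max
  k <- i
  while (k <= n && m[k] < open_level && (k - i) < cap) k <- k + 1L
  dwell <- (k - i) / rate
  if (dwell < config$t1_min || k > n) return(NULL)
  p1_min <- min(m[i:(k - 1L)])
  # phase 2: peak within t2_max of phase-1 end
  k2_end <- min(n, k + floor(config$t2_max * rate))
  w2 <- m[k:k2_end]
  peak_idx <- k - 1L + which.max(w2)
  p2_peak <- m[peak_idx]
  # phase 3: rest fraction over the full t3_min window after the peak
  k3_end <- peak_idx + as.integer(round(config$t3_min * rate))
  if (k3_end > n) return(NULL)
  p3_rest <- mean(abs(m[(peak_idx + 1L):k3_end] - config$gravity_ref) <=
                    config$rest_tol)
  stats <- c(p1_min = p1_min, p2_peak = p2_peak, p3_rest_frac = p3_rest)
  list(stats = stats, kind = classify_candidate(stats, config),
       impact_idx = k, end_idx = k3_end)
}

#' Detect falls and near falls in a trace
#'
#' Scans the per-sample acceleration magnitude left to right. Every sample
#' below the relaxed free-fall ceiling (`freefall_max / (1 - near_margin)`,
#' the loosest level that could still yield a near fall) is tried as a
#' phase-1 start; the three phase statistics are measured and the candidate
#' is classified by [classify_candidate()]. Emitted events are
#' non-overlapping and separated by at least `refractory` seconds; the
#' scan resumes after the refractory window and the consumed rest window.
#'
#' @param trace an [accel_trace()]; resampled to 100 Hz if recorded at a
#'   different rate.
#' @param config a [threshold_config()].
#' @return A `detection_log` data frame (see [detection_events()]), sorted
#'   by `t_impact` (the phase-2 onset time). A trace too short to contain
#'   all three phases yields an empty log.
#' @export
detect_events <- function(trace, config = threshold_config()) {
  stopifnot(inherits(trace, "accel_trace"))
  validate_config(config)
  trace <- resample_trace(trace, 100)
  m <- magnitude(trace)
  n <- length(m)
  rate <- trace$rate
  out <- detection_events()
  if (n / rate < config$t1_min + config$t2_max + config$t3_min) return(out)
  open_level <- config$freefall_max / (1 - config$near_margin)
  acc <- list()
  i <- 1L
  while (i <= n) {
    if (m[i] < open_level) {
      cand <- candidate_at(m, i, rate, config)
      if (!is.null(cand) && cand$kind != "none") {
        acc[[length(acc) + 1L]] <- cand
        i <- max(cand$end_idx + 1L,
                 cand$impact_idx + as.integer(ceiling(config$refractory * rate)) + 1L)
        next
      }
    }
    i <- i + 1L
  }
  if (!length(acc)) return(out)
  detection_events(
    kind = vapply(acc, `[[`, "", "kind"),
    t_impact = trace$t0 + (vapply(acc, `[[`, 1L, "impact_idx") - 1L) / rate,
    p1_min = vapply(acc, function(c) c$stats[["p1_min"]], 1),
    p2_peak = vapply(acc, function(c) c$stats[["p2_peak"]], 1),
    p3_rest_frac = vapply(acc, function(c) c$stats[["p3_rest_frac"]], 1))
}

#' Per-subject threshold calibration
#'
#' Emulates the per-wearer optimization performed during test falls: a
#' grid search over multiplicative scalings of `freefall_max`,
#' `impact_min` and `rest_tol` that maximizes the number of labelled
#' calibration falls detected, breaking ties by the number of false fall
#' alarms on an optional walking (nonfall) trace and then by proximity to
#' the base configuration (smallest total absolute log scaling).
#'
#' @param calibration list of calibration recordings, each a list with
#'   elements `trace` (an [accel_trace()]) and `event` (a one-row
#'   `event_log` marking the induced fall). The study protocol allows one
#'   to three such test falls.
#' @param base starting [threshold_config()].
#' @param walking optional [accel_trace()] of free walking used to penalize
#'   false alarms.
#' @param grid numeric vector of multiplicative scalings tried for each of
#'   the three thresholds (default `c(0.7, 0.85, 1, 1.15, 1.3)`).
#' @param tolerance_s a detected fall within this many seconds of the
#'   labelled event counts as detecting it (default 10).
#' @return A `threshold_config`. With an empty calibration set, `base` is
#'   returned unchanged with a warning.
#' @export
calibrate_thresholds <- function(calibration, base = threshold_config(),
                                 walking = NULL,
                                 grid = c(0.7, 0.85, 1.0, 1.15, 1.3),
                                 tolerance_s = 10) {
  validate_config(base)
  if (!length(calibration)) {
    warning("empty calibration set; returning base configuration")
    return(base)
  }
  combos <- expand.grid(sf = grid, si = grid, sr = grid,
                        KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    sc <- combos[r, ]
    cfg <- unclass(base)
    cfg$freefall_max <- base$freefall_max * sc$sf
    cfg$impact_min <- base$impact_min * sc$si
    cfg$rest_tol <- base$rest_tol * sc$sr
    cfg <- tryCatch(do.call(threshold_config, cfg), error = function(e) NULL)
    if (is.null(cfg)) next
    hits <- sum(vapply(calibration, function(cal) {
      det <- detect_events(cal$trace, cfg)
      det <- det[det$kind == "fall", , drop = FALSE]
      any(abs(det$t_impact - cal$event$t_start) <= tolerance_s |
            (det$t_impact >= cal$event$t_start &
               det$t_impact <= cal$event$t_end))
    }, NA) %in% TRUE)
    fa <- if (is.null(walking)) 0L else
      sum(detect_events(walking, cfg)$kind == "fall")
    dist <- sum(abs(log(c(sc$sf, sc$si, sc$sr))))
    score <- list(cfg = cfg, hits = hits, fa = fa, dist = dist)
    if (is.null(best) || hits > best$hits ||
        (hits == best$hits && fa < best$fa) ||
        (hits == best$hits && fa == best$fa && dist < best$dist - 1e-12))
      best <- score
  }
  best$cfg
}
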