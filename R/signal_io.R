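#' wristfall: threshold-based smartwatch fall detection and evaluation
#'
#' Tools for detecting falls and near falls in wrist-worn tri-axial
#' accelerometer signals with a three-phase threshold state machine, for
#' simulating induced-fall study sessions with ground-truth event logs, and
#' for computing the full diagnostic-accuracy battery (sensitivity,
#' specificity, predictive values, likelihood ratios, accuracy) with exact
#' and log-method confidence intervals.
#'
#' @section Main entry points:
#' * [accel_trace()], [read_trace()], [write_trace()], [magnitude()] —
#'   signal containers and I/O.
#' * [threshold_config()], [detect_events()], [classify_candidate()],
#'   [calibrate_thresholds()] — the detector.
#' * [sim_params()], [protocol_spec()], [simulate_session()],
#'   [simulate_study()] — the synthetic study generator.
#' * [match_events()], [diagnostic_stats()], [clopper_pearson()],
#'   [stratified_report()] — blinded evaluation.
#' * [fw_main()] — command-line front end (see `inst/cli/fallwatch`).
#'
#' @keywords internal
"_PACKAGE"

EVENT_KINDS <- c("fall", "near_fall", "nonfall_segment")
FALL_DIRECTIONS <- c("forward", "backward", "left", "right", "none")

#' Tri-axial wrist accelerometer trace
#'
#' A uniformly sampled tri-axial acceleration series in g units (gravity
#' included, so a stationary watch reads magnitude about 1 g). Implied
#' sample timestamps are `t0 + (k - 1) / rate` seconds for sample `k`.
#'
#' @param data numeric matrix (or data frame) with columns `ax`, `ay`, `az`
#'   in g; one row per sample.
#' @param rate sampling rate in Hz (> 0). The detector operates at 100 Hz;
#'   traces at other rates are resampled by [resample_trace()].
#' @param t0 start time in seconds from session start.
#' @return An object of class `accel_trace`: a list with elements `data`
#'   (n x 3 matrix), `rate`, `t0`.
#' @seealso [read_trace()], [magnitude()], [trace_times()]
#' @examples
#' tr <- accel_trace(cbind(ax = 0, ay = 0, az = rep(1, 100)), rate = 100)
#' range(magnitude(tr))
#' @export
accel_trace <- function(data, rate = 100, t0 = 0) {
  data <- as.matrix(data)
  if (ncol(data) != 3L)
    stop("accelerometer data must have exactly 3 columns (ax, ay, az)")
  if (nrow(data) < 1L) stop("trace must contain at least one sample")
  storage.mode(data) <- "double"
  colnames(data) <- c("ax", "ay", "az")
  if (!all(is.finite(data))) stop("all sample components must be finite")
  if (!is.finite(rate) || rate <= 0) stop("sampling rate must be > 0")
  if (!is.finite(t0)) stop("t0 must be finite")
  structure(list(data = data, rate = as.numeric(rate), t0 = as.numeric(t0)),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf("<accel_trace> %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              n, x$rate, x$t0, x$t0 + (n - 1) / x$rate))
  invisible(x)
}

#' @export
length.accel_trace <- function(x) nrow(x$data)

#' Sample timestamps of a trace
#'
#' @param trace an [accel_trace()].
#' @return Numeric vector of timestamps in seconds, one per sample.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  trace$t0 + (seq_len(nrow(trace$data)) - 1L) / trace$rate
}

#' Per-sample acceleration magnitude
#'
#' Euclidean norm of `(ax, ay, az)` per sample, in g. This is the scalar
#' series the threshold detector scans: it is invariant under axis
#' permutation and sign flips, so watch orientation does not matter.
#'
#' @param trace an [accel_trace()].
#' @return Numeric vector, same length as the trace.
#' @export
magnitude <- function(trace) {
  stopifnot(inherits(trace, "accel_trace"))
  sqrt(rowSums(trace$data^2))
}

#' Linearly resample a trace to a target rate
#'
#' The detector's thresholds are stated at a 100 Hz working rate; traces
#' recorded at other rates are linearly interpolated onto the working grid.
#'
#' @param trace an [accel_trace()].
#' @param rate target sampling rate in Hz (default 100).
#' @return An [accel_trace()] at `rate`. Returned unchanged if the rate
#'   already matches.
#' @export
resample_trace <- function(trace, rate = 100) {
  stopifnot(inherits(trace, "accel_trace"))
  if (isTRUE(all.equal(trace$rate, rate))) return(trace)
  t_old <- trace_times(trace)
  t_new <- seq(t_old[1L], t_old[length(t_old)], by = 1 / rate)
  data <- vapply(1:3, function(j)
    stats::approx(t_old, trace$data[, j], xout = t_new)$y,
    numeric(length(t_new)))
  accel_trace(data, rate = rate, t0 = trace$t0)
}

#' Read an accelerometer trace from CSV
#'
#' Expects a header `t,ax,ay,az`; time in seconds, axes in g. Timestamps
#' must be strictly increasing and uniformly spaced (tolerance 1e-6 s);
#' the sampling rate is inferred from the median timestamp spacing.
#'
#' @param path path to a trace CSV file.
#' @return An [accel_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("t", "ax", "ay", "az")))
    stop("trace CSV must have header t,ax,ay,az: ", path)
  if (nrow(df) < 1L) stop("trace CSV has no samples: ", path)
  bad <- which(!stats::complete.cases(df) |
                 !apply(is.finite(as.matrix(df)), 1L, all))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1L] + 1L, path))
  if (nrow(df) > 1L) {
    dt <- diff(df$t)
    nm <- which(dt <= 0)
    if (length(nm))
      stop(sprintf("non-monotone time at line %d of %s", nm[1L] + 2L, path))
    step <- stats::median(dt)
    nu <- which(abs(dt - step) > 1e-6)
    if (length(nu))
      stop(sprintf("non-uniform sampling at line %d of %s (spacing %g, expected %g)",
                   nu[1L] + 2L, path, dt[nu[1L]], step))
    rate <- 1 / step
  } else {
    rate <- 100
  }
  accel_trace(as.matrix(df[, c("ax", "ay", "az")]), rate = rate, t0 = df$t[1L])
}

#' Write an accelerometer trace to CSV
#'
#' Writes header `t,ax,ay,az` with enough digits for a lossless
#' round-trip through [read_trace()] (better than 1e-9).
#'
#' @param trace an [accel_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "accel_trace"))
  df <- data.frame(t = trace_times(trace), trace$data)
  old <- options(digits = 15, scipen = 100)
  on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a reference event log
#'
#' Ground-truth events for a session: induced falls and near falls with a
#' direction, and explicit nonfall (free-walking) segments that serve as
#' the negative instances in evaluation.
#'
#' @param kind character vector over `fall`, `near_fall`, `nonfall_segment`.
#' @param direction character vector over `forward`, `backward`, `left`,
#'   `right`, `none`; `none` if and only if the kind is `nonfall_segment`.
#' @param t_start,t_end event interval in seconds, `t_end >= t_start`.
#' @return A data frame of class `event_log`, sorted by `t_start`.
#' @export
reference_events <- function(kind = character(), direction = character(),
                             t_start = numeric(), t_end = numeric()) {
  df <- data.frame(kind = as.character(kind),
                   direction = as.character(direction),
                   t_start = as.numeric(t_start),
                   t_end = as.numeric(t_end),
                   stringsAsFactors = FALSE)
  validate_events(df)
  df <- df[order(df$t_start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

validate_events <- function(df) {
  bad_kind <- setdiff(unique(df$kind), EVENT_KINDS)
  if (length(bad_kind))
    stop("unknown event kind: ", paste(bad_kind, collapse = ", "))
  bad_dir <- setdiff(unique(df$direction), FALL_DIRECTIONS)
  if (length(bad_dir))
    stop("unknown fall direction: ", paste(bad_dir, collapse = ", "))
  if (any(df$t_end < df$t_start))
    stop("event t_end must be >= t_start")
  mism <- (df$direction == "none") != (df$kind == "nonfall_segment")
  if (any(mism))
    stop("direction must be 'none' exactly for nonfall_segment events")
  invisible(df)
}

#' Read / write a reference event log
#'
#' CSV with header `kind,direction,t_start,t_end`. Rows need not be sorted
#' on disk; [read_events()] returns them sorted by `t_start`.
#'
#' @param path path to an event CSV file.
#' @return [read_events()]: an `event_log` data frame; [write_events()]:
#'   the path, invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character",
                                       "numeric", "numeric"))
  if (!identical(names(df), c("kind", "direction", "t_start", "t_end")))
    stop("event CSV must have header kind,direction,t_start,t_end: ", path)
  reference_events(df$kind, df$direction, df$t_start, df$t_end)
}

#' @param events an `event_log` data frame (see [reference_events()]).
#' @rdname read_events
#' @export
write_events <- function(events, path) {
  validate_events(events)
  old <- options(digits = 15, scipen = 100)
  on.exit(options(old))
  utils::write.csv(as.data.frame(events)[, c("kind", "direction",
                                             "t_start", "t_end")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detection events emitted by the detector
#'
#' One row per emitted event: the kind (`fall` or `near_fall`), the impact
#' time `t_impact` (onset of the impact phase) and the three measured phase
#' statistics: minimum magnitude during free fall (`p1_min`), peak impact
#' magnitude (`p2_peak`) and post-impact rest fraction (`p3_rest_frac`).
#'
#' @param kind,t_impact,p1_min,p2_peak,p3_rest_frac parallel vectors.
#' @return A data frame of class `detection_log`, sorted by `t_impact`.
#' @export
detection_events <- function(kind = character(), t_impact = numeric(),
                             p1_min = numeric(), p2_peak = numeric(),
                             p3_rest_frac = numeric()) {
  df <- data.frame(kind = as.character(kind),
                   t_impact = as.numeric(t_impact),
                   p1_min = as.numeric(p1_min),
                   p2_peak = as.numeric(p2_peak),
                   p3_rest_frac = as.numeric(p3_rest_frac),
                   stringsAsFactors = FALSE)
  if (!all(df$kind %in% c("fall", "near_fall")))
    stop("detection kind must be 'fall' or 'near_fall'")
  if (nrow(df) && !all(is.finite(as.matrix(df[, -1L]))))
    stop("detection statistics must be finite")
  df <- df[order(df$t_impact), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("detection_log", "data.frame")
  df
}

#' Read / write a detection log
#'
#' CSV with header `kind,t_impact,p1_min,p2_peak,p3_rest_frac`.
#'
#' @param path path to a detections CSV file.
#' @return [read_detections()]: a `detection_log` data frame;
#'   [write_detections()]: the path, invisibly.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  detection_events(df$kind, df$t_impact, df$p1_min, df$p2_peak,
                   df$p3_rest_frac)
}

#' @param detections a `detection_log` data frame.
#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  old <- options(digits = 15, scipen = 100)
  on.exit(options(old))
  utils::write.csv(as.data.frame(detections), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
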