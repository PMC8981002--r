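# Independent oracles and fixture builders. Everything here is written
# with plain scalar loops, deliberately sharing no code with the package.

# Build a z-axis trace from a magnitude vector.
mag_trace <- function(mag, rate = 100, t0 = 0) {
  accel_trace(cbind(ax = 0, ay = 0, az = mag), rate = rate, t0 = t0)
}

# Piecewise-constant magnitude: segments is a list of c(value, duration_s).
piecewise_mag <- function(segments, rate = 100) {
  unlist(lapply(segments, function(s) rep(s[[1]], round(s[[2]] * rate))))
}

# Canonical fixture: 5 s at 1 g, 0.3 s free-fall dip at 0.3 g, a 0.05 s
# spike of given amplitude, then ~1 g rest for 3 s.
canonical_fixture <- function(spike_amp, rate = 100) {
  spike <- pmax(1, spike_amp * sin(pi * seq_len(5) / 6))
  rest <- 1 + 0.02 * sin(seq_len(3 * rate))
  mag_trace(c(rep(1, 5 * rate), rep(0.3, 0.3 * rate), spike, rest),
            rate = rate)
}

# Brute-force detector oracle: tries EVERY sample index as a phase-1
# start, evaluates the three phase predicates directly, and greedily
# accepts events left to right under the overlap/refractory rules.
oracle_detect <- function(trace, config = threshold_config()) {
  m <- sqrt(rowSums(trace$data^2))
  n <- length(m)
  rate <- trace$rate
  res <- list()
  if (n / rate < config$t1_min + config$t2_max + config$t3_min)
    return(res)
  open_level <- config$freefall_max / (1 - config$near_margin)
  keep <- 1 - config$near_margin
  i <- 1L
  while (i <= n) {
    ok <- FALSE
    if (m[i] < open_level) {
      # phase 1 dwell
      k <- i
      while (k <= n && m[k] < open_level &&
             (k - i) < floor(config$t1_max * rate)) k <- k + 1L
      if ((k - i) / rate >= config$t1_min && k <= n) {
        p1 <- min(m[i:(k - 1L)])
        k2 <- min(n, k + floor(config$t2_max * rate))
        peak_idx <- k
        for (j in k:k2) if (m[j] > m[peak_idx]) peak_idx <- j
        p2 <- m[peak_idx]
        k3 <- peak_idx + round(config$t3_min * rate)
        if (k3 <= n) {
          inside <- 0L
          for (j in (peak_idx + 1L):k3)
            if (abs(m[j] - config$gravity_ref) <= config$rest_tol)
              inside <- inside + 1L
          p3 <- inside / (k3 - peak_idx)
          full <- p1 <= config$freefall_max && p2 >= config$impact_min &&
            p3 >= config$rest_frac_min
          relax <- p1 <= config$freefall_max / keep &&
            p2 >= config$impact_min * keep &&
            p3 >= config$rest_frac_min * keep
          kind <- if (full) "fall" else if (relax) "near_fall" else "none"
          if (kind != "none") {
            res[[length(res) + 1L]] <- list(
              kind = kind, t_impact = trace$t0 + (k - 1L) / rate,
              stats = c(p1, p2, p3))
            i <- max(k3 + 1L,
                     k + as.integer(ceiling(config$refractory * rate)) + 1L)
            ok <- TRUE
          }
        }
      }
    }
    if (!ok) i <- i + 1L
  }
  res
}

# Exact binomial interval by bisection on the binomial CDF (no qbeta).
oracle_clopper_pearson <- function(x, n, conf_level = 0.95, iters = 60L) {
  a <- (1 - conf_level) / 2
  bisect <- function(f, target) {
    lo <- 0; hi <- 1
    for (i in seq_len(iters)) {
      mid <- (lo + hi) / 2
      if (f(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bisect(function(p) 1 - pbinom(x - 1, n, p), a)       # P(X >= x) = a
  upper <- if (x == n) 1 else
    1 - bisect(function(p) pbinom(x, n, 1 - p), a)       # P(X <= x) = a
  c(lower, upper)
}

# Brute-force matching oracle: enumerates every injective assignment of
# detections to reference events within tolerance and keeps one with the
# most matches (so tp is the maximum attainable).
oracle_match_tp <- function(det_times, ref, tolerance) {
  nd <- length(det_times)
  nr <- nrow(ref)
  dist <- function(t, j)
    max(0, max(ref$t_start[j] - t, t - ref$t_end[j]))
  cnt <- function(i, used) {
    if (i > nd) return(length(used))
    m <- cnt(i + 1L, used)
    for (j in seq_len(nr)) {
      if (j %in% used) next
      if (dist(det_times[i], j) <= tolerance)
        m <- max(m, cnt(i + 1L, c(used, j)))
    }
    m
  }
  cnt(1L, integer())
}

# Random valid trace for round-trip property tests.
random_trace <- function(n = NULL) {
  if (is.null(n)) n <- sample(1:200, 1)
  accel_trace(matrix(runif(3 * n, -4, 4), ncol = 3),
              rate = sample(c(50, 100, 128), 1),
              t0 = runif(1, 0, 10))
}

default_profile <- function(side = "left")
  subject_profile(170, 65, watch_side = side)
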