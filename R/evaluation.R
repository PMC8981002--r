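#' Confusion table for one event class
#'
#' Non-negative TP/FP/FN/TN counts of detector events against the video
#' reference standard.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return A list of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(round(counts)), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Match detections against a reference log
#'
#' Blinded comparison: greedy one-to-one matching in time order. Each
#' detection of the selected kind matches the nearest still-unmatched
#' reference event of that kind within `tolerance_s` (distance zero inside
#' the event interval) and counts as a true positive; unmatched detections
#' are false positives and unmatched reference events false negatives.
#' Negative instances are the explicit `nonfall_segment` entries of the
#' log (for the near-fall analysis, reference falls also count as
#' negatives, mirroring the study's "all falls, normal falls" negative
#' set); a negative with no unmatched detection inside its interval is a
#' true negative.
#'
#' @param detected a `detection_log` (see [detection_events()]), sorted by
#'   `t_impact`.
#' @param reference an `event_log` (see [reference_events()]), sorted by
#'   `t_start`.
#' @param kind `"fall"` or `"near_fall"`: which analysis to run.
#' @param tolerance_s matching tolerance in seconds (> 0; default 10 —
#'   protocol falls are spaced further apart than this, so results are
#'   insensitive to the exact value).
#' @return A [confusion_table()]. The per-reference match indicator is
#'   attached as attribute `"matched_reference"` (logical, one entry per
#'   reference event of the kind, in time order).
#' @export
match_events <- function(detected, reference, kind = c("fall", "near_fall"),
                         tolerance_s = 10) {
  kind <- match.arg(kind)
  if (!is.finite(tolerance_s) || tolerance_s <= 0)
    stop("configuration error: tolerance_s must be > 0")
  if (is.unsorted(detected$t_impact)) stop("detections must be sorted by t_impact")
  if (is.unsorted(reference$t_start)) stop("reference events must be sorted by t_start")
  det <- detected[detected$kind == kind, , drop = FALSE]
  ref <- reference[reference$kind == kind, , drop = FALSE]
  matched_ref <- rep(FALSE, nrow(ref))
  det_matched <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(det))) {
    ti <- det$t_impact[i]
    d <- pmax(0, pmax(ref$t_start - ti, ti - ref$t_end))
    d[matched_ref] <- Inf
    if (length(d) && min(d) <= tolerance_s) {
      j <- which.min(d)
      matched_ref[j] <- TRUE
      det_matched[i] <- TRUE
    }
  }
  tp <- sum(det_matched)
  fp <- sum(!det_matched)
  fn <- sum(!matched_ref)
  neg <- reference[reference$kind == "nonfall_segment" |
                     (kind == "near_fall" & reference$kind == "fall"), ,
                   drop = FALSE]
  fp_times <- det$t_impact[!det_matched]
  tn <- sum(vapply(seq_len(nrow(neg)), function(j)
    !any(fp_times >= neg$t_start[j] & fp_times <= neg$t_end[j]), NA))
  ct <- confusion_table(tp, fp, fn, tn)
  attr(ct, "matched_reference") <- matched_ref
  ct
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles: the lower bound is the
#' `alpha/2` quantile of `Beta(x, n - x + 1)` (0 when `x = 0`) and the
#' upper bound the `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when
#' `x = n`).
#'
#' @param x number of successes, `0 <= x <= n`.
#' @param n number of trials, `>= 1`.
#' @param conf_level confidence level in (0, 1), default 0.95.
#' @return Numeric vector `c(lower, upper)` of proportions.
#' @examples
#' round(100 * clopper_pearson(174, 226), 2)  # 70.95 82.31
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  if (!is.finite(x) || !is.finite(n) || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n))
    stop("require integer 0 <= x <= n, n >= 1")
  if (!(conf_level > 0 && conf_level < 1))
    stop("conf_level must be in (0, 1)")
  a <- 1 - conf_level
  lower <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Log-method confidence intervals for likelihood ratios
#'
#' Intervals of the form `exp(log(LR) +/- z * se)` with
#' `se(log LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` and the
#' analogous form (fn and tn in place of tp and fp) for LR-. A ratio whose
#' formula involves a zero count is flagged undefined (`NA` with a note).
#'
#' @param ct a [confusion_table()].
#' @param conf_level confidence level, default 0.95.
#' The critical value is the conventional two-decimal normal deviate
#' (1.96 at the 95% level), the convention of the diagnostic-accuracy
#' calculators this method is stated for.
#'
#' @return List with elements `lr_pos` and `lr_neg`, each
#'   `c(est, lower, upper)` or all-`NA` with a `"note"` attribute when
#'   undefined.
#' @export
lr_ci_log_method <- function(ct, conf_level = 0.95) {
  z <- wald_z(conf_level)
  n1 <- ct$tp + ct$fn
  n0 <- ct$fp + ct$tn
  one <- function(num_hits, den_hits, note_zero) {
    # LR+ : num = tp (of n1), den = fp (of n0); LR- : num = fn, den = tn
    if (num_hits == 0 || den_hits == 0 || n1 == 0 || n0 == 0) {
      out <- c(est = NA_real_, lower = NA_real_, upper = NA_real_)
      attr(out, "note") <- note_zero
      return(out)
    }
    lr <- (num_hits / n1) / (den_hits / n0)
    se <- sqrt(1 / num_hits - 1 / n1 + 1 / den_hits - 1 / n0)
    c(est = lr, lower = exp(log(lr) - z * se), upper = exp(log(lr) + z * se))
  }
  list(lr_pos = one(ct$tp, ct$fp, "undefined (no false positives)"),
       lr_neg = one(ct$fn, ct$tn, "undefined (no true negatives)"))
}

# conventional two-decimal normal deviate used by the Wald-type (log /
# logit) intervals: 1.96 at 95%, 2.58 at 99%
wald_z <- function(conf_level) round(stats::qnorm(1 - (1 - conf_level) / 2), 2)

# prevalence-based standard logit interval for a predictive value;
# var(logit PPV) = (1-se)/(se n1) + sp/((1-sp) n0), NPV analogous.
logit_pv_ci <- function(pv, var_logit, z) {
  if (!is.finite(pv) || pv <= 0 || pv >= 1 || !is.finite(var_logit))
    return(c(NA_real_, NA_real_))
  l <- stats::qlogis(pv)
  se <- sqrt(var_logit)
  stats::plogis(c(l - z * se, l + z * se))
}

#' Full diagnostic-accuracy report from a confusion table
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, predictive
#' values, accuracy, likelihood ratios and the tabulation-convention error
#' rates, each with a 95% (by default) confidence interval where defined:
#' exact Clopper-Pearson for sensitivity, specificity and accuracy;
#' prevalence-based standard logit intervals for PPV and NPV; the log
#' method for the likelihood ratios. Statistics with a zero denominator
#' are flagged undefined (`NA` estimate plus a note) while the others are
#' still returned.
#'
#' `fp_rate` and `fn_rate` follow the study's tabulation convention —
#' denominators are the test-positive and test-negative column totals, so
#' they equal `1 - PPV` and `1 - NPV`; the conventional complement of
#' specificity is exposed separately as `fall_out` (`fp/(fp+tn)`).
#'
#' @param ct a [confusion_table()].
#' @param conf_level confidence level, default 0.95.
#' @return A list of class `diagnostic_report`: per statistic a numeric
#'   `c(est, lower, upper)` (proportions as fractions, ratios on their own
#'   scale), plus `counts` and `conf_level`.
#' @examples
#' rep <- diagnostic_stats(confusion_table(174, 3, 52, 265))
#' print(rep)
#' @export
diagnostic_stats <- function(ct, conf_level = 0.95) {
  stopifnot(inherits(ct, "confusion_table"))
  if (!(conf_level > 0 && conf_level < 1))
    stop("conf_level must be in (0, 1)")
  z <- wald_z(conf_level)
  n1 <- ct$tp + ct$fn   # condition positive
  n0 <- ct$fp + ct$tn   # condition negative
  tpos <- ct$tp + ct$fp # test positive
  tneg <- ct$fn + ct$tn # test negative
  n <- n1 + n0
  prop_cp <- function(x, den, note) {
    if (den == 0) {
      out <- c(est = NA_real_, lower = NA_real_, upper = NA_real_)
      attr(out, "note") <- note
      return(out)
    }
    ci <- clopper_pearson(x, den, conf_level)
    c(est = x / den, lower = ci[[1L]], upper = ci[[2L]])
  }
  sens <- prop_cp(ct$tp, n1, "undefined (no condition positives)")
  spec <- prop_cp(ct$tn, n0, "undefined (no condition negatives)")
  acc <- prop_cp(ct$tp + ct$tn, n, "undefined (empty table)")
  se <- sens[["est"]]; sp <- spec[["est"]]
  pv <- function(x, den, var_logit, note) {
    if (den == 0) {
      out <- c(est = NA_real_, lower = NA_real_, upper = NA_real_)
      attr(out, "note") <- note
      return(out)
    }
    p <- x / den
    ci <- logit_pv_ci(p, var_logit, z)
    c(est = p, lower = ci[[1L]], upper = ci[[2L]])
  }
  ppv <- pv(ct$tp, tpos,
            if (n1 > 0 && n0 > 0 && se > 0 && sp < 1)
              (1 - se) / (se * n1) + sp / ((1 - sp) * n0) else NA_real_,
            "undefined (no test positives)")
  npv <- pv(ct$tn, tneg,
            if (n1 > 0 && n0 > 0 && se < 1 && sp > 0)
              se / ((1 - se) * n1) + (1 - sp) / (sp * n0) else NA_real_,
            "undefined (no test negatives)")
  lr <- lr_ci_log_method(ct, conf_level)
  rate <- function(x, den) if (den == 0) NA_real_ else x / den
  structure(list(
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    accuracy = acc, lr_pos = lr$lr_pos, lr_neg = lr$lr_neg,
    fp_rate = rate(ct$fp, tpos), fn_rate = rate(ct$fn, tneg),
    fall_out = rate(ct$fp, n0),
    counts = ct, conf_level = conf_level), class = "diagnostic_report")
}

fmt_pct <- function(v) {
  if (!is.finite(v[[1L]])) {
    note <- attr(v, "note")
    return(if (is.null(note)) "N/A" else paste("N/A,", note))
  }
  if (length(v) >= 3L && is.finite(v[[2L]]))
    sprintf("%.2f (%.2f-%.2f)", 100 * v[[1L]], 100 * v[[2L]], 100 * v[[3L]])
  else sprintf("%.2f", 100 * v[[1L]])
}

fmt_ratio <- function(v) {
  if (!is.finite(v[[1L]])) {
    note <- attr(v, "note")
    return(if (is.null(note)) "N/A" else paste("N/A,", note))
  }
  sprintf("%.2f (%.2f-%.2f)", v[[1L]], v[[2L]], v[[3L]])
}

#' Format a diagnostic report as an aligned text table
#'
#' @param x a `diagnostic_report`.
#' @param ... unused.
#' @return Character vector of table lines (percent values to two
#'   decimals, the study's table convention).
#' @export
format.diagnostic_report <- function(x, ...) {
  lab <- sprintf("%d%% CI", round(100 * x$conf_level))
  c(sprintf("%-33s %s", paste0("Statistic (", lab, ")"), "Value"),
    sprintf("%-33s %s", "Sensitivity (%)", fmt_pct(x$sensitivity)),
    sprintf("%-33s %s", "Specificity (%)", fmt_pct(x$specificity)),
    sprintf("%-33s %s", "Positive likelihood ratio", fmt_ratio(x$lr_pos)),
    sprintf("%-33s %s", "Negative likelihood ratio", fmt_ratio(x$lr_neg)),
    sprintf("%-33s %s", "Positive predictive value (%)", fmt_pct(x$ppv)),
    sprintf("%-33s %s", "Negative predictive value (%)", fmt_pct(x$npv)),
    sprintf("%-33s %s", "Accuracy (%)", fmt_pct(x$accuracy)),
    sprintf("%-33s %s", "False-positive rate (%)",
            if (is.finite(x$fp_rate)) sprintf("%.1f", 100 * x$fp_rate) else "N/A"),
    sprintf("%-33s %s", "False-negative rate (%)",
            if (is.finite(x$fn_rate)) sprintf("%.1f", 100 * x$fn_rate) else "N/A"))
}

#' @export
print.diagnostic_report <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}

#' Chi-square comparison of two sensitivities
#'
#' 2x2 chi-square test (detected vs missed, group A vs group B) on the
#' condition-positive rows of two confusion tables, without continuity
#' correction.
#'
#' @param ct_a,ct_b [confusion_table()]s with `tp + fn > 0`.
#' @return List with `statistic`, `p_value` and `df`.
#' @export
compare_sensitivities <- function(ct_a, ct_b) {
  m <- rbind(a = c(detected = ct_a$tp, missed = ct_a$fn),
             b = c(detected = ct_b$tp, missed = ct_b$fn))
  if (any(rowSums(m) == 0)) stop("both groups need condition positives")
  if (any(colSums(m) == 0)) stop("degenerate table: an expected cell is 0")
  if (identical(m["a", ] * sum(m["b", ]), m["b", ] * sum(m["a", ])))
    return(list(statistic = 0, p_value = 1, df = 1L))
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Run the detector over a simulated study and label every instance
#'
#' Applies [detect_events()] to each session, matches detections against
#' the reference log for both event kinds and returns one row per
#' instance: reference falls and near falls (`outcome` `tp` or `fn`),
#' false alarms (`fp`) and nonfall segments with no alarm (`tn`), each
#' carrying its stratum labels (fall `direction`, watch-relative `side`
#' — ipsilateral/contralateral for side falls — and `device` model).
#'
#' @param study output of [simulate_study()].
#' @param config a [threshold_config()].
#' @param tolerance_s matching tolerance in seconds.
#' @return A data frame with columns `subject_id`, `device`, `kind`,
#'   `direction`, `side`, `outcome`.
#' @export
evaluate_study <- function(study, config = threshold_config(),
                           tolerance_s = 10) {
  rows <- lapply(study, function(sess) {
    det <- detect_events(sess$trace, config)
    side_of <- function(direction) {
      ifelse(direction %in% c("left", "right"),
             ifelse(direction == sess$profile$watch_side,
                    "ipsilateral", "contralateral"),
             "other")
    }
    per_kind <- function(kind) {
      ct <- match_events(det, sess$events, kind, tolerance_s)
      ref <- sess$events[sess$events$kind == kind, , drop = FALSE]
      hit <- attr(ct, "matched_reference")
      pos <- if (nrow(ref)) data.frame(
        kind = kind, direction = ref$direction, side = side_of(ref$direction),
        outcome = ifelse(hit, "tp", "fn")) else NULL
      negk <- if (kind == "fall") data.frame(
        kind = kind, direction = "none", side = "other",
        outcome = c(rep("fp", ct$fp), rep("tn", ct$tn))) else NULL
      rbind(pos, negk)
    }
    out <- rbind(per_kind("fall"), per_kind("near_fall"))
    if (is.null(out) || !nrow(out)) return(NULL)
    data.frame(subject_id = sess$subject_id, device = sess$device, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

outcomes_to_ct <- function(outcome) {
  confusion_table(sum(outcome == "tp"), sum(outcome == "fp"),
                  sum(outcome == "fn"), sum(outcome == "tn"))
}

#' Stratified diagnostic reports with pairwise sensitivity comparisons
#'
#' Splits instance-level evaluation records by a stratum label, computes a
#' confusion table and [diagnostic_stats()] per stratum, and compares
#' every pair of strata with [compare_sensitivities()] at the 0.05
#' significance level, without multiplicity adjustment (the study's
#' procedure). Strata without condition positives are omitted with a
#' warning.
#'
#' @param records data frame from [evaluate_study()] (or with columns
#'   `outcome` and the stratum variable).
#' @param by stratum column name, e.g. `"direction"`, `"side"`, `"device"`.
#' @param kind restrict to one event kind when a `kind` column is present.
#' @param conf_level confidence level for per-stratum reports.
#' @return A list with `strata` (named list of `diagnostic_report`s),
#'   `tables` (named list of confusion tables) and `comparisons` (data
#'   frame of pairwise chi-square results with a `significant` flag at
#'   p < 0.05).
#' @export
stratified_report <- function(records, by, kind = NULL, conf_level = 0.95) {
  if (!by %in% names(records)) stop("no such stratum column: ", by)
  if (!is.null(kind) && "kind" %in% names(records))
    records <- records[records$kind == kind, , drop = FALSE]
  groups <- split(records, records[[by]], drop = TRUE)
  tables <- lapply(groups, function(g) outcomes_to_ct(g$outcome))
  ok <- vapply(tables, function(ct) ct$tp + ct$fn > 0, NA)
  if (any(!ok))
    warning("omitting strata without condition positives: ",
            paste(names(tables)[!ok], collapse = ", "))
  tables <- tables[ok]
  reports <- lapply(tables, diagnostic_stats, conf_level = conf_level)
  nm <- names(tables)
  comparisons <- NULL
  if (length(nm) >= 2L) {
    pairs <- utils::combn(nm, 2L)
    comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      cmp <- tryCatch(compare_sensitivities(tables[[a]], tables[[b]]),
                      error = function(e) list(statistic = NA_real_,
                                               p_value = NA_real_))
      data.frame(stratum_a = a, stratum_b = b,
                 chi_square = cmp$statistic, p_value = cmp$p_value,
                 significant = isTRUE(cmp$p_value < 0.05))
    }))
  }
  list(strata = reports, tables = tables, comparisons = comparisons)
}
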