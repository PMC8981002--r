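ref8 <- reference_events(
  kind = c(rep("fall", 8), rep("nonfall_segment", 2)),
  direction = c(rep(c("forward", "backward", "left", "right"), 2),
                "none", "none"),
  t_start = c(seq(10, 150, by = 20), 200, 260),
  t_end = c(seq(11, 151, by = 20), 250, 300))

test_that("an absent detector yields pure false negatives", {
  ct <- match_events(detection_events(), ref8, "fall", 10)
  expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
               list(tp = 0L, fp = 0L, fn = 8L, tn = 2L))
})

test_that("matching honours the time tolerance", {
  near <- detection_events("fall", 14, 0.3, 3, 0.95)   # 4 s within tolerance
  ct <- match_events(near, ref8, "fall", 10)
  expect_equal(ct$tp, 1L); expect_equal(ct$fn, 7L); expect_equal(ct$fp, 0L)
  far <- detection_events("fall", 500, 0.3, 3, 0.95)   # 30+ s from any fall
  ct <- match_events(far, ref8, "fall", 10)
  expect_equal(ct$tp, 0L); expect_equal(ct$fp, 1L)
  expect_error(match_events(near, ref8, "fall", -1), "configuration error")
})

test_that("greedy matching attains the brute-force assignment optimum", {
  set.seed(81)
  for (rep in 1:20) {
    nr <- sample(1:4, 1)
    starts <- sort(runif(nr, 0, 300))
    starts <- starts[c(TRUE, diff(starts) > 25)]  # protocol-like spacing
    ref <- reference_events(rep("fall", length(starts)),
                            rep("forward", length(starts)),
                            starts, starts + 1.5)
    td <- sort(runif(sample(0:4, 1), 0, 300))
    det <- detection_events(rep("fall", length(td)), td,
                            rep(0.3, length(td)), rep(3, length(td)),
                            rep(0.95, length(td)))
    ct <- match_events(det, ref, "fall", 10)
    expect_equal(ct$tp, oracle_match_tp(td, ref, 10))
    expect_equal(ct$tp + ct$fn, nrow(ref))            # conservation
    expect_lte(ct$tp, nrow(det))
  }
})

test_that("matching is invariant to input order once sorted", {
  set.seed(91)
  td <- sort(runif(5, 0, 300))
  det <- detection_events(rep("fall", 5), td, rep(0.3, 5), rep(3, 5),
                          rep(0.95, 5))
  ct1 <- match_events(det, ref8, "fall", 10)
  perm <- sample(nrow(ref8))
  ref_shuffled <- reference_events(ref8$kind[perm], ref8$direction[perm],
                                   ref8$t_start[perm], ref8$t_end[perm])
  ct2 <- match_events(det, ref_shuffled, "fall", 10)
  expect_equal(unclass(ct1)[1:4], unclass(ct2)[1:4])
  bad <- det; bad$t_impact <- rev(bad$t_impact); class(bad) <- "data.frame"
  expect_error(match_events(bad, ref8, "fall", 10), "sorted")
})

test_that("near-fall negatives include reference falls", {
  ref <- reference_events(c("fall", "near_fall", "nonfall_segment"),
                          c("forward", "left", "none"),
                          c(10, 50, 100), c(11, 51, 200))
  ct <- match_events(detection_events(), ref, "near_fall", 10)
  expect_equal(ct$fn, 1L)
  expect_equal(ct$tn, 2L)   # the fall and the walking segment
})

test_that("clopper_pearson matches the CDF-bisection oracle and boundaries", {
  set.seed(111)
  for (rep in 1:40) {
    n <- sample(1:400, 1)
    x <- sample(0:n, 1)
    expect_equal(unname(clopper_pearson(x, n)),
                 oracle_clopper_pearson(x, n), tolerance = 1e-6)
  }
  expect_equal(clopper_pearson(0, 50)[["lower"]], 0)
  expect_equal(clopper_pearson(343, 343)[["upper"]], 1)
  expect_equal(clopper_pearson(343, 343)[["lower"]], 0.9893, tolerance = 1e-4)
  expect_error(clopper_pearson(5, 4), "0 <= x <= n")
  expect_error(clopper_pearson(1, 2, conf_level = 1.2), "conf_level")
})

test_that("diagnostic point estimates are invariant under count scaling", {
  ct1 <- confusion_table(174, 3, 52, 265)
  ct3 <- confusion_table(3 * 174, 3 * 3, 3 * 52, 3 * 265)
  r1 <- diagnostic_stats(ct1); r3 <- diagnostic_stats(ct3)
  for (s in c("sensitivity", "specificity", "ppv", "npv", "accuracy",
              "lr_pos", "lr_neg")) {
    expect_equal(r3[[s]][["est"]], r1[[s]][["est"]])
    expect_lte(r3[[s]][["upper"]] - r3[[s]][["lower"]],
               r1[[s]][["upper"]] - r1[[s]][["lower"]])  # CIs narrow
  }
})

test_that("transposition swaps sensitivity/PPV and specificity/NPV", {
  ct <- confusion_table(206, 0, 43, 343)
  tr <- confusion_table(206, 43, 0, 343)   # transposed table
  a <- diagnostic_stats(ct); b <- diagnostic_stats(tr)
  expect_equal(b$accuracy[["est"]], a$accuracy[["est"]])
  expect_equal(b$sensitivity[["est"]], a$ppv[["est"]])
  expect_equal(b$ppv[["est"]], a$sensitivity[["est"]])
  expect_equal(b$specificity[["est"]], a$npv[["est"]])
  expect_equal(b$npv[["est"]], a$specificity[["est"]])
})

test_that("a perfect detector reports 100% everywhere defined", {
  r <- diagnostic_stats(confusion_table(7, 0, 0, 5))
  for (s in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    expect_equal(r[[s]][["est"]], 1)
  expect_true(is.na(r$lr_pos[["est"]]))   # no false positives
  expect_equal(r$fp_rate, 0); expect_equal(r$fn_rate, 0)
})

test_that("undefined statistics are flagged while others are returned", {
  r <- diagnostic_stats(confusion_table(0, 0, 0, 10))
  expect_true(is.na(r$sensitivity[["est"]]))
  expect_match(attr(r$sensitivity, "note"), "condition positives")
  expect_equal(r$specificity[["est"]], 1)
  expect_true(is.na(r$ppv[["est"]]))
})

test_that("log-method LR intervals collapse to the point at level -> 0", {
  ct <- confusion_table(174, 3, 52, 265)
  tight <- lr_ci_log_method(ct, conf_level = 1e-9)
  expect_equal(tight$lr_pos[["lower"]], tight$lr_pos[["est"]], tolerance = 1e-6)
  expect_equal(tight$lr_pos[["upper"]], tight$lr_pos[["est"]], tolerance = 1e-6)
  undef <- lr_ci_log_method(confusion_table(5, 0, 2, 10))
  expect_true(all(is.na(undef$lr_pos)))
  expect_match(attr(undef$lr_pos, "note"), "false positives")
})

test_that("chi-square sensitivity comparison matches direct arithmetic", {
  a <- confusion_table(90, 0, 10, 0)
  b <- confusion_table(50, 0, 50, 0)
  got <- compare_sensitivities(a, b)
  # direct O/E arithmetic on the 2x2 (detected vs missed) table
  O <- rbind(c(90, 10), c(50, 50))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(got$statistic, sum((O - E)^2 / E))
  expect_equal(got$p_value, pchisq(got$statistic, 1, lower.tail = FALSE))
  # identical groups -> no difference
  same <- compare_sensitivities(a, a)
  expect_equal(same$statistic, 0); expect_equal(same$p_value, 1)
  # symmetry under group order
  rev <- compare_sensitivities(b, a)
  expect_equal(rev$statistic, got$statistic)
  expect_equal(rev$p_value, got$p_value)
  expect_error(compare_sensitivities(confusion_table(0, 0, 0, 1), a),
               "condition positives")
})

test_that("stratified reports reduce to the pooled report for one stratum", {
  rec <- data.frame(kind = "fall", direction = "forward", side = "other",
                    device = "A",
                    outcome = c(rep("tp", 6), rep("fn", 2), rep("tn", 3)))
  out <- stratified_report(rec, by = "device", kind = "fall")
  expect_length(out$strata, 1L)
  pooled <- diagnostic_stats(confusion_table(6, 0, 2, 3))
  expect_equal(out$strata$A$sensitivity, pooled$sensitivity)
  expect_null(out$comparisons)
})

test_that("identical strata compare with p = 1; empty strata are dropped", {
  rec <- rbind(
    data.frame(kind = "fall", device = "A",
               outcome = c(rep("tp", 9), "fn")),
    data.frame(kind = "fall", device = "B",
               outcome = c(rep("tp", 9), "fn")))
  out <- stratified_report(rec, by = "device", kind = "fall")
  expect_equal(out$comparisons$p_value, 1)
  expect_false(out$comparisons$significant)
  rec2 <- rbind(rec, data.frame(kind = "fall", device = "C", outcome = "tn"))
  expect_warning(out2 <- stratified_report(rec2, by = "device", kind = "fall"),
                 "omitting")
  expect_length(out2$strata, 2L)
})

test_that("simulated study stratification shows the watch-side effect", {
  st <- simulate_study(8, protocol_spec(), sim_params(), seed = 19)
  rec <- evaluate_study(st)
  side <- stratified_report(rec[rec$side != "other", ], by = "side",
                            kind = "fall")
  ipsi <- side$strata$ipsilateral$sensitivity[["est"]]
  contra <- side$strata$contralateral$sensitivity[["est"]]
  expect_gte(ipsi, contra)
})
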