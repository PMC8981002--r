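---
title: "Threshold-based fall detection: model, simulator and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based fall detection: model, simulator and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristfall)
```

## The detection model

The detector operates on the per-sample Euclidean magnitude
$\lVert a \rVert = \sqrt{a_x^2 + a_y^2 + a_z^2}$ of a wrist-worn
tri-axial accelerometer signal, in g with gravity included, so a
stationary wrist reads $\approx 1$ g. Working with the magnitude makes
the detector invariant to watch orientation (axis permutations and sign
flips), which matters because wrist orientation during a fall is
essentially arbitrary.

A fall candidate is a three-phase excursion:

* **Phase 1, free fall.** The magnitude drops below the free-fall
  ceiling `freefall_max` while the arm accelerates toward the ground.
  The dwell below the ceiling must last at least `t1_min`; dwell credit
  is capped at `t1_max` so that long sub-1 g stretches (e.g. the watch
  lying face-down on a soft surface) do not run the phase indefinitely.
* **Phase 2, impact.** Within `t2_max` of the dip ending, the magnitude
  must spike to at least `impact_min`.
* **Phase 3, rest.** Over the `t3_min` window following the impact peak,
  at least a fraction `rest_frac_min` of samples must lie in the
  "almost immobile" band `gravity_ref` ± `rest_tol`.

A candidate passing all three full-threshold predicates is a **fall**.
A candidate that fails at least one full predicate but passes all three
with each threshold relaxed by the margin `near_margin` (20% by default)
is a **near fall**: the relaxation is applied in each predicate's
permissive direction, i.e. `impact_min` and `rest_frac_min` are scaled
by $1 - m$ and `freefall_max` by $1/(1-m)$. This "all phases close"
reading of near-fall detection was chosen deliberately over the laxer
"any one phase close" alternative: a single-phase criterion fires
constantly on ordinary walking (whose magnitude regularly dips below any
relaxed free-fall ceiling), which is incompatible with the near-zero
false-alarm behaviour wrist detectors exhibit on free-living data.

Two structural consequences of the margin are worth stating. First, the
scan for candidates opens at the *relaxed* free-fall ceiling
`freefall_max / (1 − near_margin)` — the loosest level that could still
yield a near fall — so near falls whose dip never reaches the full
ceiling are not silently skipped. Second, the phase-1 dwell requirement
(`t1_min`) gates candidate formation and is not itself margin-relaxed:
the classified statistics are the dip minimum, the impact peak and the
rest fraction, and only the thresholds on those three are relaxed.

### Defaults and their rationale

| Setting | Default | Why |
|---|---|---|
| `gravity_ref` | 1 g | physical constant (9.8 m/s²) |
| `freefall_max` | 0.6 g | clearly below gravity yet above sensor noise; conventional free-fall threshold for wrist devices |
| `t1_min`, `t1_max` | 0.15 s, 0.5 s | a fall from standing height takes roughly 0.3–0.5 s; 0.15 s rejects walking dips, which last under ~0.13 s at normal cadence |
| `impact_min` | 2.5 g | wrist impacts in induced falls typically exceed 3 g; 2.5 g keeps attenuated impacts detectable |
| `t2_max` | 0.2 s | impact follows free fall nearly immediately |
| `rest_tol`, `t3_min`, `rest_frac_min` | 0.25 g, 2 s, 0.9 | "almost immobile on the ground for a long period" — 2 s at ≥ 90% quiescence excludes recovery steps |
| `near_margin` | 0.20 | the 20% "close to threshold" definition |
| `refractory` | 3 s | one physical fall produces one alert; bounce artifacts are suppressed |

Deployed watch apps do not publish their numeric thresholds; these
defaults are this package's own operating point, made fully configurable
(`threshold_config()`, serializable as `key=value` files) and
personalizable via `calibrate_thresholds()`, which mirrors the
per-wearer optimization performed on up to three test falls before a
session: a 5×5×5 grid of multiplicative scalings of `freefall_max`,
`impact_min` and `rest_tol`, maximizing detected calibration falls, with
ties broken first by false alarms on a walking trace and then by
proximity to the base configuration (smallest total |log scaling|), so
calibration never drifts without evidence.

### Numerical choices

* All threshold comparisons are **inclusive**: a statistic exactly at a
  threshold passes. This makes boundary behaviour testable rather than
  floating-point-accidental.
* `t_impact` is the phase-2 onset (first sample at or above the open
  level after the dip), accurate to one sample of the 100 Hz working
  grid.
* The phase-3 window must fit entirely inside the trace; a candidate
  truncated by the end of the recording is dropped rather than scored on
  a partial window.
* Every sample below the open level is tried as a phase-1 start (the
  scan advances one sample on rejection), so the detector is exactly
  equivalent to a brute-force per-sample candidate scan; the test suite
  asserts this against an independent loop-based oracle.
* Traces recorded at other rates are linearly resampled to the 100 Hz
  working rate (the app-level collection interval of 0.01 s), treating
  higher advertised sensor frequencies as hardware detail below the
  algorithm.

## The synthetic study generator

`simulate_session()` emulates the standard induced-fall validation
protocol: per participant, two rounds of four directed falls (forward,
right, left, backward — hence 8 falls, 2 per direction), induced by an
unexpected push, separated by ~20 s of free walking, optionally preceded
by up to three excluded calibration test falls and followed by
step-recovery near falls. The reference log carries one `fall` event per
induced fall, one `near_fall` per near fall and one explicit
`nonfall_segment` per walking interval. `simulate_study()` draws
subject profiles uniformly from the cohort ranges reported for such
experiments (height 153–184 cm, weight 47–110 kg), alternates the watch
wrist and cycles device models.

Signal shapes are deliberately simple — a flat noisy dip, a half-sine
impact, a sinusoidal gait — because the detector consumes only the three
phase statistics; what matters is where those statistics land relative
to the thresholds:

* **Ipsilateral falls** draw an impact peak around 3.2 ± 0.25 g and a
  dip around 0.3 g: comfortably across both full thresholds, detected
  essentially always.
* **Contralateral side falls** attenuate the dip excursion and peak by
  `contralateral_atten = 0.75`, placing the mean peak (2.4 g) just below
  `impact_min` = 2.5 g, so detection becomes a coin weighted by the
  per-fall jitter — this is what produces the ipsilateral >
  contralateral sensitivity gap seen in wrist-worn studies, and with 2
  of 8 falls contralateral it puts overall study sensitivity in the
  0.80–0.85 band.
* **Near falls** scale the fall signature by `near_fall_scale = 0.85`
  and replace the rest plateau with 2 s of recovery steps at amplitude
  `recovery_amp = 0.26` g, chosen so the rest fraction lands around
  0.82 — inside the relaxed-but-not-full band [0.72, 0.90) — making the
  segment a near fall by the phase-3 predicate.
* **Walking** oscillates at 2 Hz with amplitude 0.3 g: its dips below
  the open level last ~0.09 s, under `t1_min`, and its peaks stay far
  below any impact threshold, so walking generates no events — matching
  the near-zero false-positive rates such detectors report.

These amplitudes were fixed once, from the geometry above, as the
package's definition of the study conditions.

What the generator does **not** emulate: biomechanical arm dynamics,
orientation tracking (the axis composition merely rotates a magnitude
profile into a direction-biased unit vector), sampling dropouts,
device-specific noise spectra (devices differ only by an amplitude
scale), or activities of daily living beyond level walking. Passing the
end-to-end tests therefore shows the pipeline is internally consistent
and directionally faithful — not that the default thresholds would
achieve any particular sensitivity on real wrist data.

## Evaluation methods

`match_events()` performs the blinded comparison: greedy one-to-one
matching of detections (by `t_impact`) to reference events of the same
kind, nearest first in time order, within a ±10 s tolerance (events in
the protocol are ≥ 20 s apart, so any tolerance between the impact
duration and the inter-fall spacing gives identical results). Unmatched
detections are false positives, unmatched reference events false
negatives. Negative instances must be *explicit*: true negatives are the
logged nonfall segments (for the near-fall analysis, reference falls
also count as negative instances, matching the "everything except a near
fall" convention), because a diagnostic table is meaningless without an
enumerable negative class.

`diagnostic_stats()` computes the standard battery. Confidence
intervals:

* sensitivity, specificity, accuracy — exact Clopper–Pearson from beta
  quantiles, cross-checked in the tests against a binomial-CDF bisection
  oracle to 1e-6 over every (x, n) with n ≤ 200;
* likelihood ratios — the log method,
  $\exp(\ln LR \pm z\,\mathrm{se}(\ln LR))$ with
  $\mathrm{se}(\ln LR^+) = \sqrt{1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)}$;
* PPV and NPV — prevalence-based standard logit intervals
  (Mercaldo-type), e.g.
  $\widehat{var}(\mathrm{logit}\,PPV) = \frac{1-se}{se\,n_1} + \frac{sp}{(1-sp)\,n_0}$.

The Wald-type (log and logit) intervals use the conventional
two-decimal normal deviate (1.96 at the 95% level) rather than the
exact quantile 1.959964: this is the convention of the
diagnostic-accuracy calculators these methods come from, and at n in
the hundreds it moves bounds only in the second decimal.

Two tabulation conventions deserve a note. The reported
"false-positive rate" and "false-negative rate" of such studies use the
*test-result column totals* as denominators — `fp/(tp+fp)` and
`fn/(fn+tn)`, i.e. 1−PPV and 1−NPV — not the epidemiological
1−specificity, which is exposed separately as `fall_out`. And a
confusion table read with its axes transposed swaps sensitivity with
PPV and specificity with NPV while leaving accuracy unchanged; the test
suite demonstrates this equivalence, which explains how published
tables occasionally print a predictive value under a sensitivity label.
Where a printed table is internally inconsistent with its own counts,
this package follows the counts.

Statistics with empty denominators (e.g. LR⁺ with zero false positives)
are flagged undefined with an explanatory note rather than returned as
infinities, and the remaining statistics are still computed.

`compare_sensitivities()` uses the 2×2 chi-square without continuity
correction on the detected/missed split, and `stratified_report()`
applies it pairwise across strata (direction, watch-relative side,
device model) at the 0.05 level without multiplicity adjustment —
deliberately matching the analysis procedure of the studies this
package evaluates, not current best inferential practice.

## Problem sizes

The test suite exercises: property tests at 10–200 random cases per
invariant; detector-vs-oracle equivalence on piecewise traces of up to
2,000 samples; the full Clopper–Pearson grid n ≤ 200 (20,300 intervals,
vectorized bisection); and an end-to-end synthetic study of 22 subjects
× 8 falls × 10 seeds (1,760 scored falls). The whole suite runs in
about half a minute on one CPU.

## Known limitations

* The default thresholds are an operating point chosen from fall-
  detection convention, not disclosed values of any commercial app;
  absolute sensitivities on real data depend on them.
* Greedy nearest-first matching is not a globally optimal assignment;
  under protocol-like event spacing (≥ 2× tolerance) the two coincide,
  which the tests verify by enumeration on small cases.
* The simulator's watch-side effect is inserted by construction
  (`contralateral_atten`); it demonstrates the direction of the effect,
  not its published magnitude.
* Near-fall semantics ("all phases close") is one reading of an
  ambiguous field definition; the margin direction and the all-phases
  requirement are documented choices, configurable via `near_margin`.
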