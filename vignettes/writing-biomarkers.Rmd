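---
title: "Writing-process digital biomarkers: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Writing-process digital biomarkers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphomarker)
```

## The screening problem

People with mild cognitive impairment due to Alzheimer's disease (MCI)
show subtle slowing of information processing and executive dysfunction
well before conventional scales flag them. A short touch-screen writing
task — writing the six-stroke Chinese character for "rice" (米) ten
times with the index finger, within a three-minute limit — produces a
timestamped event stream rich enough to quantify those deficits: how
long the subject hesitates before starting, how long and how variably
they pause between strokes, how fast and how evenly they move while the
finger is on the glass, and whether the stroke order and character
count come out right.

`graphomarker` implements the full analysis chain for this paradigm:
session validation and storage, stroke segmentation, the 21 digital
biomarkers, the two-group statistical battery with stepwise logistic
screening and ROC evaluation, and a calibrated synthetic-session
generator that makes every stage testable without clinical data.

## Segmentation and the biomarker battery

A session is an ordered stream of `(t_ms, x_px, y_px, phase)` events
with integer-millisecond timestamps, pixel coordinates (origin
top-left, y down) and phases forming `(down move* up)*`. Segmentation
pairs each finger-down with its finger-up; everything downstream works
on the resulting strokes (duration $t_j$, polyline length $D_j$, speed
$v_j = D_j/t_j$), the $J-1$ inter-stroke gaps $g_j$, the initial pause,
and the total time. The decomposition

$$\text{total} = \text{initial pause} + \sum_j t_j + \sum_j g_j$$

holds exactly by construction, and the package asserts the implied
identities (`IPSDB_1 = IPSDB_3 + IPSDB_4`, `IPSDB_4 = IPSDB_5 +
IPSDB_6`, `EFDB_5 = J · EFDB_7`, ...) to machine precision in its test
suite.

The ten information-processing-speed biomarkers (IPSDB) are timing and
pause features; the eleven executive-function biomarkers (EFDB) cover
stroke count, trajectory length, speed and the task score. Their exact
definitions are in `?biomarkers`. Points worth calling out:

* **Coefficients of variation use the population (divide-by-n) standard
  deviation.** The variability features are CVs of the gaps, the stroke
  lengths and the stroke speeds; the population form is used
  consistently.
* **Single-stroke sessions** have no gaps; the gap statistics are
  returned as `NA` and excluded pairwise downstream, never silently
  zeroed.
* **The within-stroke pause count** (`IPSDB_10`) counts stationary runs
  of identical consecutive coordinates inside strokes. The raw
  duplicate-pair reading is available at `min_pause_ms = 0`; the
  default threshold of 50 ms counts maximal runs at least that long,
  which de-couples the feature from the device sampling rate (at 60 Hz
  a single duplicated sample spans only ~17 ms and would otherwise
  dominate the count).
* **The task score** (`EFDB_1`, range 0–2) has two binary components:
  the detected character count equals ten, and every character's
  temporal stroke order matches the dictionary order. Characters are
  detected by spatial grouping of stroke centroids against a running
  character centroid, with a threshold of 1.9 × the median per-stroke
  bounding-box dimension — the median is robust to occasional
  oversized strokes, and the factor separates the worst within-character
  excursion (~1.4 units) from the nearest between-character distance
  (~2.5 units). Stroke order is matched per character by nearest
  template stroke on a scale-invariant descriptor (centroid plus unit
  start-to-end direction). The rubric is deliberately simple and
  isolated in `score_task()` so it can be replaced wholesale.

### Reconciling the published formulae

The published equation set for these biomarkers contains several typos
that contradict the accompanying verbal definitions and units; the
package follows the verbal definitions throughout: total trajectory
length sums over **all** J strokes; maximum trajectory length is the
maximum of the per-stroke **lengths** (pixels, not seconds); per-stroke
speed is $D_j/t_j$ with the maximum/mean/CV taken over those J speeds.
Similarly, two published variability rows print values like 84.64 and
57.48, which are only sensible as CV × 100; the reference tables in
`reference_group_summaries()` store them divided by 100, on the same
unitless scale the package computes. Finally, the printed total-task-time
row has its group cells in an order that contradicts both the text and
the row's own components (a total cannot be smaller than the sum of its
parts); the default reference follows the text direction, and
`columns_as_printed = TRUE` preserves the printed order for anyone who
wants the table verbatim.

## The cohort statistics

`compare_groups()` routes each marker: Shapiro–Wilk at α = 0.05 per
group (constant samples count as non-normal); both groups normal →
classical independent-samples t-test with mean ± SD descriptives;
otherwise Mann–Whitney U with median (IQR). The U test is exact by
enumeration when both groups have at most 7 untied values and otherwise
uses the normal approximation with tie and continuity corrections.
Categorical demographics use Pearson's chi-square without continuity
correction — that choice reproduces the published sex comparison
(p = 0.738) exactly. Raw p < 0.05 defines significance, as in the
original analysis; a Benjamini–Hochberg column is reported for
information only.

`stepwise_logistic()` is a bidirectional p-value stepwise on
likelihood-ratio tests (entry 0.05, removal 0.10), run on standardised
candidates so selection is invariant to affine rescaling, with the
final model refit on the original scale. No installed package offers
p-value-based stepwise with LR tests (AIC-based stepping is a different
procedure), so this is implemented here, with a ridge-stabilised IRLS
fallback under complete separation. `roc_auc()` wraps pROC for the
curve and the DeLong interval (bootstrap optional); the pipeline
auto-orients per-marker ROCs so AUC ≥ 0.5 and records the orientation.
`sample_size_ttest()` searches the smallest per-group n whose
noncentral-t power meets the target; at the screening design
(d = 0.7, α = 0.05, power = 0.8, two-sided, ratio 1) it returns
34 + 34 = 68, matching the published a priori computation.

```{r}
sample_size_ttest(d = 0.7)
```

## The synthetic-session generator

No raw subject data are deposited for this paradigm, so the generator
is a first-class component: it emulates the study conditions so that
extracted biomarker distributions — across subjects — match the
published per-group medians/IQRs (38 MCI, 34 HC). It is hierarchical:

* **Between subjects**, each latent (initial pause, gap level, gap
  variability, base stroke duration, slowdown tail, glyph scale, style
  spread, freeze rate) is log-normal; medians are calibrated, and the
  log-scale sigmas are set from the published IQRs by log-normal
  quantile matching. Log-normality is an assumption — only
  medians/IQRs or means ± SDs are published, and these strongly
  right-skewed summaries are consistent with it — and it is isolated
  in this module.
* **Within a session**, gaps are log-normal around the subject's gap
  level (the nine between-character gaps carry a group-specific
  multiplier: 1.1 for controls, 2.5 for MCI — between-character
  planning pauses are longer, much more so in MCI), individual gaps are
  capped at 15 s, and stroke timing follows the isochrony principle of
  handwriting: a stroke takes the subject's base duration times a
  right-skewed slowdown factor `exp(E)`, `E ~ Exp` truncated at 4,
  regardless of stroke extent, subject to the subject's personal
  ceiling on sweep speed (log-normal with median 1350 px/s in *both*
  groups — peak sweep speed is limited by the hand, not by cognition —
  and group spreads quantile-matched to the published maximum-speed
  IQRs). Stationary "freezes" are injected inside strokes at a Poisson
  rate (held for 70 ms in controls, 170 ms in MCI), which both drives
  the pause count and adds slow-stroke outliers.
* **Glyph geometry**: each subject draws six personal per-template-stroke
  length multipliers (their "style", clamped to [0.4, 2.5]) whose
  spread itself varies between subjects — the dominant source of the
  large published spread in trajectory-length variability. Characters
  are laid out on a 5-per-row grid; coordinates get 1 px of vertex
  noise and integer-pixel quantisation; events are emitted at 60 Hz
  with integer-millisecond timestamps.
* **Task errors**: a session scrambles within-character stroke order
  with probability 0.62 (HC) / 0.70 (MCI) and writes 9 or 11 characters
  with probability 0.58 / 0.72 — rates chosen from the closed-form
  score distribution so the task-score medians land on the published
  1 (HC) and 0 (MCI).

The isochrony assumption is forced by the published summaries
themselves: writing time × average speed ≈ total trajectory length
holds in the published numbers only if speed scales with stroke length
(for any independent speed model the arithmetic–harmonic mean
inequality would push the product above the printed value). Likewise
the group-equal speed ceilings reflect that the published maximum
stroke speeds are nearly equal across groups while mean speed and speed
variability differ strongly — impossible for any smooth i.i.d. speed
model, but natural if peak sweep speed is limited by the hand rather
than by cognition. The ceiling median sits where the published
(mean speed, speed CV) pair becomes jointly reachable; the cost is that
simulated maximum speeds run some 15–20% above the published medians,
the residue of that internal inconsistency.

### Calibration

`calibrate_sim_params()` ties each of eight target markers to one
generative knob (initial pause, gap level, gap CV, freeze rate, glyph
scale, style spread, base stroke duration, slowdown tail) and iterates:
simulate a probe set per group, measure achieved medians, scale each
knob by `(target/achieved)^damping`. Parameters whose targets are
already inside tolerance are left untouched, updates are bounded inside
ranges where the marker responses are monotone (outside them some
responses invert — e.g. once the slowdown tail saturates its
truncation, speed variability *falls* as the tail grows), and the
initial pause is set analytically since the extracted value *is* the
latent. The shipped defaults are the output of this calibration against
the published tables, frozen; the acceptance suite re-verifies every
target median within 10% at n = 500 sessions per group.

Two published target pairs sit on (or slightly beyond) the boundary of
what any single generative family can satisfy simultaneously — the
published per-group (mean speed, speed CV) pair, and the pause-family
(mean gap, max gap, gap CV) triple, each internally inconsistent for
any i.i.d. within-subject model at the printed magnitudes. The shipped
calibration places every individual target within the 10% tolerance
while preserving the printed between-group ratios; the residual cost is
visible in the battery as a slightly over-eager average-speed contrast
(published p = 0.059, just missing significance; the synthetic cohorts
cross p < 0.05 more often than not) and an under-powered
writing-efficiency contrast.

### What passing tests do and do not show

The generator reproduces *marginal per-group biomarker distributions*
and the qualitative group separation. It does not attempt
biomechanically realistic trajectories (no jerk minimisation, no
curvature–speed coupling), between-marker correlation structure beyond
what the shared primitives induce, longitudinal or learning effects, or
device artefacts other than sampling, quantisation and vertex noise.
Tests passing on synthetic cohorts therefore validate the *pipeline* —
segmentation, feature math, routing, selection, ROC — under realistic
marginals; they are not evidence about real patients, and the published
subject-level AUCs (0.918 joint, 0.783/0.859 for the scales) are not
reproducible without the original cohort. On calibrated synthetic
cohorts the joint model typically reaches AUC > 0.9, qualitatively
consistent with the published separation.

```{r, eval = FALSE}
cohort <- simulate_cohort_table(n_mci = 38, n_hc = 34, seed = 1)
report <- run_screening_pipeline(cohort)
report
glance(report)
autoplot(report)
```

## Numerical and design notes

* Raw time is integer milliseconds in files; all biomarker math is in
  seconds from segmentation onward. Coordinates are device pixels
  (top-left origin). Sessions exceeding the 3-minute limit are flagged
  invalid and excluded, mirroring the paradigm rule, never truncated.
* Simulated sessions are byte-identical given (parameters, group,
  seed), with fixed RNG kinds, and cohort child seeds derive
  deterministically from the master seed; simulation never perturbs the
  caller's RNG state.
* Problem sizes used by the automated checks: 50 replicate cohorts of
  38 + 34 subjects for the battery-size check; 500 sessions per group
  for calibration verification; 1000 sessions for the identity suite;
  100 sessions for oracle equivalence; 100 seeds per stepwise scenario.
* Ties in the Mann–Whitney statistic route to the corrected normal
  approximation; the exact route requires untied data. Zero-duration
  strokes with positive extent (possible in principle from a corrupt
  stream) are excluded from speed statistics with a warning.
* The stepwise entry/removal thresholds, the routing alpha, the
  significance alpha, the ROC interval method and the pause threshold
  are all carried in `screening_config()`; defaults follow the
  published analysis where it states a value.

## Known limitations

* The task-score rubric is the simplest testable reading of "order
  correct and count correct"; the original scoring rules (partial
  credit, penalties) are not recoverable and anything learned from
  `EFDB_1` on synthetic data is conditional on this rubric.
* Character detection assumes characters are written in spatially
  separated positions (as the paradigm's grid layout enforces);
  heavily overlapping writing would need a different grouping rule.
* Single-pointer streams only: multi-touch input is rejected at
  validation.
* The generator's feasibility compromises above mean two derived
  markers sit slightly off the published significance boundary; see
  the calibration section.
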