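---
title: "Methods: spatiotemporal gait analysis for vestibulopathy cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal gait analysis for vestibulopathy cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestgait)
```

## What the pipeline computes

`vestgait` implements the computational chain of a clinical gait study
comparing bilateral vestibulopathy (BV), chronic unilateral vestibulopathy
(UV) and healthy subjects (HS) walking overground on a 10-m walkway at three
self-selected speeds (slow, comfortable, fast; three trials per condition,
optical motion capture at 100 Hz):

1. marker trajectories in (CSV dialect), gap filling by marker
   inter-correlation reconstruction;
2. automatic foot-strike / foot-off detection with per-trial self-selection
   among candidate methods;
3. gait-cycle segmentation (foot strike to ipsilateral foot strike) and 13
   per-cycle spatiotemporal parameters;
4. dimensionless normalization by leg length and gravity;
5. clinical gait scores (FGA, TUG, tandem walk, DHI) with their categorical
   bands;
6. group statistics: Shapiro-Wilk screening, Kruskal-Wallis with Dunn post
   hocs for clinical scores, a mixed-model repeated-measures analysis of
   per-cycle parameters, and one-stage FDR control;
7. SPSS-style two-step cluster analysis of symptom scores versus functional
   scores.

Every stage is exercised against a synthetic walker with exactly known
ground truth, so the whole chain is testable without any external recording.

## The synthetic walker

`walker_spec()` / `generate_walk()` build a kinematic template, not a
physical simulation. Its purpose is to have *exact* events and parameters:

* The pelvis (SACR marker) advances at constant speed
  `v = step_length x cadence / 60`, with a 2 cm sinusoidal lateral sway and
  a small vertical bob at twice the step frequency.
* Each foot is exactly stationary in the horizontal plane throughout its
  stance phase. During swing, the heel travels one stride with velocity
  `v + cycloid bump`: the bump is zero at toe-off and heel strike, so swing
  velocity never falls below the pelvis speed. A pure cycloidal profile
  (zero end velocity) was rejected: it places the maximum of
  `heel_x - sacrum_x` several percent of a gait cycle before the true foot
  strike, which would make the coordinate-based detector systematically
  wrong by construction rather than by measurement error. With the
  bump-over-carrier profile, the extrema of the detection signals coincide
  exactly with the true events, and ground contact is purely geometric
  (heel height zero, zero horizontal velocity) -- no force plates are
  simulated.
* Timing is symmetric: with stance fraction `f`, each double-support period
  is `f - 0.5` of the cycle, total double support `2f - 1`, single support
  `1 - f`. These identities are what the tests assert.
* Noise is isotropic Gaussian per coordinate, added after the template;
  dropout (missing frames) is applied after noise. Both are governed by a
  seed.

Each trial is one straight pass along the walkway; back-and-forth protocols
are represented by alternating the `direction` of consecutive trials, and
the event/cycle machinery accepts explicit exclusion windows for turns. The
simulation window starts a quarter cycle before the first recorded strike so
every ground-truth event is an interior sample.

What the template does *not* emulate: soft-tissue artifact, foot
deformation and heel-pivot during loading, stance-phase micro-motion,
cadence drift, pathological asymmetries of timing (only spatial asymmetry is
parameterized), and turning. Passing tests on this template therefore
demonstrate correctness of the computation chain, not clinical validity of
the detectors on real vestibulopathy gait.

## Event detection and its refinement

Two detectors run per trial and side, both in a travel-aligned frame
(rotation about the vertical axis so pelvis displacement is +x, which makes
both walkway directions uniform):

* **coordinate**: strikes at local maxima of `heel_x - sacrum_x`, offs at
  local minima of `toe_x - sacrum_x`;
* **velocity**: strike and off candidates where the smoothed horizontal
  foot speed falls below / rises above 10% of the mean pelvis speed, with
  below-threshold runs shorter than 0.15 s discarded as blips.

Signals are smoothed with a zero-phase 2nd-order Butterworth low-pass at
6 Hz (the standard choice for 100 Hz gait kinematics; configurable). Because
zero-phase filtering rounds the velocity-discontinuity corner at each event,
raw extrema of the smoothed signal are biased by 2-4 frames. Candidates are
therefore refined by a local changepoint fit: during stance,
`foot_x - sacrum_x` falls along a line of known slope (minus the pelvis
advance per frame), so `lev(f) = y(f) + vpf * f` is constant; for each
candidate changepoint the stance-side frames are scored by squared deviation
from their common level and the swing-side frames by a one-sided envelope
penalty (the foot must depart from the stance line by at least the pelvis
advance per frame, with half a frame of slack beyond the first frame because
the true event generally falls between samples). The minimizer is exact on
the noiseless template and behaves as a least-squares changepoint estimator
under marker noise. Ties -- an event exactly between two samples -- break
toward the later frame for both strikes and offs, which keeps phase
durations unbiased.

Candidates within 20 frames of the trial boundary (35 for the velocity
method, whose differentiated signal has longer filter edge transients) are
discarded rather than guessed.

Method self-selection replaces an operator's visual check: each method's
combined event list is scored by strict left/right alternation of strikes,
low coefficient of variation of stride times, and stance fractions within
55-75 %GC (equal weights); the best score wins, ties break by fixed method
order (coordinate first). Strikes violating alternation in the winning list
carry a QC flag, and unusable trials are excluded with a recorded reason.
The minimum event spacing of 0.35 s corresponds to a cadence ceiling of
about 171 steps/min, above any self-selected walking cadence.

## Parameters, aggregation, normalization

A cycle runs from a foot strike to the next ipsilateral strike and must
contain, strictly ordered, the contralateral off, contralateral strike and
ipsilateral off. Footprints are heel-marker horizontal positions at strike
frames. Step width is the perpendicular distance from the contralateral
footprint to the line of progression through the cycle's two ipsilateral
footprints; a degenerate line invalidates the cycle. Cadence is cycle-local
(`120 / stride time`) so that every record is a valid unit of observation
for the mixed model; walking speed is stride length over stride time. The
extended set (stride length/time, step time, swing %, pelvis-based stride
speed, step-length asymmetry ratio) completes the 13 parameters; which six
parameters beyond the canonical seven a given clinical report uses varies,
and this choice is flagged in the package's own outputs.

Trial aggregation reports arithmetic means and sample SDs (n-1); an SD over
a single cycle is reported missing, and trials with fewer than two valid
cycles are excluded and logged.

Dimensionless normalization divides lengths by leg length `L0`, times by
`sqrt(L0/g)` and speeds by `sqrt(g*L0)`; cadence in steps/min is multiplied
by `sqrt(L0/g)` *without* converting minutes to seconds -- the only
convention that reproduces the published dimensionless cadence magnitudes
(about 26-42) while preserving the identity
`speed = step length x cadence / 60` in dimensionless form. `g` defaults to
9.81 m/s^2 and is configurable. Body mass is recorded in the anthropometry
but no parameter here is mass-dependent, so no mass scaling is invented.
Percentages of the gait cycle and ratios are unchanged, and
`from_dimensionless()` is the exact inverse.

## Clinical scores

FGA: ten items scored 0-3, total 0-30; non-integer items are rejected
(fractional values arise only from averaging scores, never from raw
scoring). TUG categories: under 10 s normal, 10-20 s good, over 29 s
impaired; times in (20, 29] fall in a band the scale does not name and are
reported as `uncategorized` rather than silently assigned; 12 s and above
flags elevated fall risk. DHI bands: 0 none, 16-34 mild, 36-52 moderate,
54-100 severe; 1-15, 35 and 53 are `unbanded`. `group_summary()` reports
median, min, max, mean and n with pairwise missing-value exclusion.

The bundled `example_dhi_cohort()` carries the per-patient DHI totals of a
published 10+10+10 vestibulopathy cohort (one BV value missing). Its group
entries in the published summary table, although headed "median (min-max)",
are reproduced by the group *means* after integer rounding (UV 267/10 =
26.7 -> 27; BV 324/9 = 36), not by the medians (17 and 40); the package
computes both and uses the mean as the reproduction target, keeping the
missing BV subject excluded (n = 9 reproduces the printed value exactly).

## Group statistics

Clinical scores are compared with Kruskal-Wallis (tie-corrected, via
`stats::kruskal.test`) and Dunn's z-tests on rank sums for all three group
pairs, two-sided, reported raw and FDR-adjusted. Shapiro-Wilk screening
annotates distributions but never switches tests automatically.

Per-cycle dimensionless parameters are analysed per speed stratum (the
published per-speed summary table implies stratified fits; a pooled fit is
possible by passing the whole table) with a linear mixed model: group fixed
effect, participant random intercept, REML, each valid cycle a unit of
observation. The overall group test is a Satterthwaite F (lmerTest);
pairwise contrasts are estimated marginal means (emmeans) with Satterthwaite
degrees of freedom by default (Kenward-Roger selectable). Singular fits fall
back to an ordinary linear model, flagged `singular_fit_lm_fallback` -- this
also makes the model reduce exactly to one-way ANOVA when there is one cycle
per subject, a property the tests assert. "One-stage" FDR control is
Benjamini-Hochberg (`stats::p.adjust`), with Benjamini-Yekutieli selectable
for dependent families.

The synthetic cohort generator (`generate_cohort()`) draws per-cycle values
as group mean + subject intercept + cycle noise, splitting each published
total SD as 60% between-subject and 40% within-subject variance (`icc =
0.6`) -- a typical repeatability ratio for spatiotemporal parameters and
enough to make the random effect identifiable. Group-level means and SDs
default to the published dimensionless table of the reference cohort
(`reference_gait_table()`; the comfortable-speed single-support row is taken
from the results text, as the printed table omits it). Clinical scores are
drawn from truncated normals with location = published group median and
scale = published range/4, rounded to each scale's resolution (FGA and DHI
integers, tandem halves). Under these defaults the mixed model detects the
planted speed differences in over 95% of replicates, and under a planted
null (equal group means, subject intercepts present) its type-I error is
0.05 within binomial error over 500 replicates -- both recomputed by
`scripts/acceptance.R`.

## Two-step cluster analysis

The patient subgrouping uses a continuous-variable two-step scheme:

1. **Pre-clustering**: cases (z-standardized, missing cases excluded
   upstream, input order fixed by subject id) are inserted sequentially into
   leaf entries; a case joins the nearest entry if the log-likelihood
   distance increase is below a threshold, else starts a new entry; the
   entry list is rebuilt with a doubled threshold when it exceeds a cap.
   The log-likelihood distance between summaries is
   `d(j,s) = xi_j + xi_s - xi_{j+s}` with
   `xi_v = -N_v * sum_k 0.5 * log(sigma_k^2 + sigma_vk^2)`, the overall
   variance acting as regularizer and a `1e-8` variance floor guarding
   `log(0)`.
2. **Merging and selection**: agglomerative merging by minimum
   log-likelihood distance; `BIC(k) = -2 * sum(xi) + (2*K*k + k - 1) *
   log(N)`. The parameter count includes the k-1 mixing proportions (the
   textbook Gaussian-mixture count); counting only per-cluster means and
   variances makes a single Gaussian cluster split about half the time,
   which defeats the purpose of automatic selection. Selection follows the
   two-stage ratio rule with the published defaults: if the BIC change from
   1 to 2 clusters is non-negative, k = 1; otherwise the coarse estimate is
   the largest k whose BIC-change ratio exceeds 0.04, refined by the ratio
   of successive minimum merge distances with the 1.15 jump criterion.
   Assignments are by smallest log-likelihood distance to the selected
   clusters, so no cluster can be empty.

Order sensitivity of the pre-cluster stage is documented, not emulated:
callers sort by a stable key. On well-separated planted data the full
pipeline matches brute-force 2-means (adjusted Rand index 1.0); on a single
spherical cluster it keeps k = 1 in well over 90% of seeds.

## Orchestration and reproducibility

`run_gait_study(gait_config(...))` runs the whole chain on a simulated
cohort: per subject, anthropometry (height ~ N(1.70, 0.08), leg length
0.53 x height) and per-speed dimensionless targets with subject- and
trial-level deviations; trajectories are generated, events detected, cycles
computed, normalized with the subject's own leg length, tested with the
mixed-model battery, and clinical scores are generated, tested
(Kruskal-Wallis/Dunn) and clustered on (DHI, FGA). All randomness flows from
one seed; two runs with the same seed produce byte-identical CSV outputs.
Every excluded trial or cycle appears in the exclusion log with a
machine-readable reason. Unknown configuration keys are rejected.

## Numerical choices and problem sizes

* Event refinement: 8-frame search, 8 stance frames, 5 swing frames;
  exactness on the noiseless template was verified over step lengths
  0.4-0.8 m, cadences 80-130 steps/min and stance 58-68 %GC.
* Gap filling: PCA regression on up to 12 whitened components of the
  co-observed markers (whitening prevents small but informative components
  from being dropped as numerically collinear); linear interpolation
  fallback for gaps of at most 5 frames when fewer than 3 reference markers
  are available; default gap ceiling 50 frames (0.5 s at 100 Hz), longer
  gaps stay missing and are reported.
* Simulation sizes in the test-suite and acceptance script: a 27-point
  noiseless recovery grid; 20-seed noise studies at 3 mm marker noise; 500
  null replicates for mixed-model calibration (n = 10 subjects/group, 20
  cycles each); 200 replicates for Kruskal-Wallis power; 100 seeds for the
  clustering null. These sizes give binomial standard errors comfortably
  below the margins being asserted.

## Known limitations

* The detectors assume near-stationary stance feet; severe shuffling gait
  or treadmill walking would need different methods.
* The two-step implementation is continuous-only (the DHI-versus-functional
  use case); categorical variables and SPSS's outlier handling are out of
  scope.
* The walker's noise model is white and isotropic; real marker noise is
  autocorrelated and anisotropic, so real-data event jitter will differ
  from the simulated figures.
* Full reproduction of the reference study's tables requires its deposited
  motion-capture dataset; the package points its accession-gated test at
  `options(vestgait.dataset_dir=)` and otherwise reports the dataset as
  unavailable.
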