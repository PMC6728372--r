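---
title: "Methods: simulating and decoding allocentric direction signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding allocentric direction signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`allodecode` implements a complete multivoxel pattern analysis (MVPA)
pipeline for a virtual spatial-navigation experiment in which the
allocentric direction of an environment boundary (the compass direction in
which a wall lies, independent of the observer's heading) and the
allocentric direction of a goal object are manipulated orthogonally. The
package covers the experimental design, a synthetic BOLD generator with
known ground truth, single-trial response estimation, linear decoding, and
group-level inference. Because every input is simulated, every downstream
claim the pipeline makes can be checked against planted truth.

## The task design

The environment is a 600 x 600 m plain with a 500 x 500 m explorable
centre, four distant landmarks (Mountain = N, Cathedral = S, Clock Tower =
E, City = W) and four 40 x 2 m walls, two with long axis north-south and
two east-west. Each wall exposes two usable long faces, so there are 8
*boundary sides*; each side is approached by 3 passive paths that place the
wall egocentrically front, left, or right of the observer — 24 paths in
all. A path's heading follows from compass geometry: a front path heads at
the wall; a left path has the wall 90° counterclockwise of the heading.

A scanning run presents each path 4 times (96 trials), the cue object
twice left and twice right of the path, in seeded random order. Each trial
is 8 s — 2 s passive movement, 4 s blank stationary phase, 2 s decision —
with a jittered inter-trial interval. The goal direction is the heading
rotated ±90° by cue side, and the correct response is the landmark lying
in that direction. Per run, both factors are exactly balanced: 24 trials
per direction for boundary and for goal.

Two design details were genuinely open and fixed as follows:

* **Inter-trial interval.** Only the 1 s mean is specified. We jitter
  uniformly on [0.5, 1.5] s: it keeps the mean, gives mild onset jitter,
  and keeps all 96 estimation windows inside a 445-volume run with wide
  margin (first onset at 10 s).
* **Joint balance.** The two allocentric factors are *marginally* uniform
  and mutually complete, but the joint distribution is structurally
  non-uniform: within, say, goal = N, boundary directions split 8/8/4/4.
  This is forced by the path geometry (goal = heading ± 90°, heading
  determined by side and egocentric position), and means an extremely
  strong signal for one factor can leak weakly into decoding of the
  other. `verify_balance()` therefore checks the balance properties that
  do hold — cue side, egocentric position, equal contribution of the two
  walls per direction, completeness of the other factor — rather than
  full joint uniformity.

The behavioural-phase helpers follow the same geometry: `enumerate_jrd()`
builds the 12 judgement-of-relative-direction questions (clockwise
disparity 90°/180°/270° mapping to right/behind/left), and
`occupancy_fraction()` bins exploration trajectories into the 10,000
5 x 5 m cells of the explorable area and reports time fractions inside the
eight 40 x 5 m boundary-proximity masks.

## The synthetic BOLD generator

For each ROI, `generate_condition_patterns()` draws a shared baseline
pattern plus four mutually orthonormal direction components scaled by
`effect_amplitude`; the baseline is orthogonal to all components, so all
four direction patterns have exactly equal norm and amplitude 0 makes them
identical. A run's signal is the sum over trials of the boundary pattern
plus the goal pattern for that trial's directions, each scaled by the
trial's regressor: a boxcar over the 6 s movement + stationary period
convolved with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
ratio 6) sampled at volume midpoints (TR = 2 s, 445 volumes, 14.8 min per
run).

On top of the signal sit the nuisance terms the preprocessing stages are
supposed to remove, so that their efficacy is demonstrable rather than
assumed:

* cosine drifts with periods ≥ 128 s (removable by the high-pass stage);
* a linear coupling of the first two motion parameters into voxel
  baselines (removable by confound regression); motion itself is a
  bounded random walk per parameter (±2 mm, ±0.02 rad);
* AR(1) noise (coefficient 0.3) plus white noise.

Default ROI size is 100 voxels, the order of magnitude of high-resolution
medial-temporal subfield ROIs. The default `effect_amplitude` of 0.35 was
fixed by a one-off calibration under the default noise model so that a
28-participant cohort shows clearly above-chance decoding of a planted
factor (per-participant accuracy ≈ 0.43, sd ≈ 0.09) while remaining far
from ceiling; it is a simulation constant, not an empirical effect-size
estimate — no such estimate is recoverable from group-level accuracies.

What the generator does *not* emulate: scanner physics (k-space, EPI
distortion, field inhomogeneity), spatial autocorrelation between voxels,
anatomical variability, behavioural errors or learning. Passing recovery
tests therefore shows the *analysis chain* is correct and unbiased under a
plausible noise model, not that real MTL data contain such signals.

## Nuisance removal and single-trial estimation

The order of operations is fixed as high-pass → confound regression →
per-trial GLM:

1. **High-pass (128 s).** Projection onto a discrete-cosine basis holding
   every component with period > 128 s, with the per-voxel mean re-added.
   This implements the stated contract (periods above the cut-off removed)
   rather than reproducing any particular package's running-line filter.
2. **Confound regression.** The 6 motion parameters are expanded to the
   24-regressor set (parameters, backward-difference derivatives with
   first sample 0, squares, squared derivatives), filtered with the same
   cosine basis, and regressed out per voxel with an intercept.
   Rank-deficient confound sets drop dependent columns with a warning.
3. **Additive per-trial GLM.** Each of the 96 trials is estimated in its
   own 3-column model: an unconvolved boxcar covering the three volumes
   whose acquisition midpoints fall 6–12 s after trial onset (the
   haemodynamic peak of the 2–6 s stationary phase), a union boxcar of all
   other trials, and an intercept. The boxcar window uses the midpoint
   rule, so jittered onsets still yield exactly three active volumes at
   TR = 2 s. On noiseless data this estimator recovers planted per-trial
   amplitudes to machine precision.

## Decoding

Per factor, trials in each run are grouped by direction, the within-label
order is permuted independently per run (seeded), and positional means
across the three runs give 96 samples, 24 per direction. Random pairing is
deliberate: deterministic pairing by path would preserve exactly the
nuisance conditions (heading, texture, cue side) the averaging is meant to
dilute.

Classification is a linear support vector classifier with L2
regularisation (libsvm binary machines via `e1071`, reduced one-vs-rest;
scores are argmaxed over classes). "Three outer folds using 20% of the
data" cannot be a partition of 96, so the outer loop is 3 stratified
shuffle splits with floor(0.2 x 96) = 19 held-out samples; within each
outer training set a 3-fold stratified grid search over
C ∈ {1, 10, 100, 1000} picks the inner-accuracy maximiser (ties to the
smallest C, the stronger regulariser), and the winner is refit on the full
outer-training set. Features enter as-is — betas are already filtered and
residualised — and no feature selection or scaling is applied. Inner folds
never touch outer-test samples; with ~100 features and 96 samples the
linear problem is typically separable, which also keeps libsvm convergence
fast at large C.

## Group inference

Per (ROI, factor) cell the per-participant mean accuracies feed two
authored procedures:

* **BCa interval.** Bias correction from the fraction of bootstrap means
  below the observed mean; acceleration from jackknife skewness; adjusted
  percentiles of the 10,000 bootstrap means (type-6 quantiles). Degenerate
  input yields a zero-width interval with a warning.
* **Shifted-null Monte Carlo test.** The null sample subtracts the group
  mean and adds chance (0.25), recentring the empirical distribution on
  chance while keeping its shape; 10,000 bootstrap means of the null
  sample form the null distribution, and
  p = (#{null mean ≥ observed} + 1) / (B + 1), one-tailed. Ties count
  against the alternative, the conservative choice. Note the recentring
  language in the source description applies BCa to the null
  construction; bias/acceleration corrections define adjusted *interval
  percentiles*, not a different resampling scheme, so the null here is the
  plain bootstrap of the shifted values while BCa corrections are used for
  the reported CI.

`bonferroni_alpha()` reproduces the conventional adjusted levels (0.05/6 =
0.008, 0.05/3 = 0.017).

## Problem sizes and numerical choices

Every stochastic step takes an explicit seed, and child seeds are derived
with a Lehmer-style integer mix so full runs are reproducible from one
master seed. The test suite validates the chain at these scales: full
28-participant, two-ROI cohorts for the planted-dissociation checks; a
16-participant zero-amplitude cohort for the null pipeline; 500 null
cohorts for the type-I calibration of the Monte Carlo test (rejection rate
at α = 0.05 within [0.03, 0.07]); 1,000 Gaussian replicates (n = 28,
B = 2,000) for BCa coverage (within [0.92, 0.97]); 100 label-free
simulations for the chance-centredness of nested-CV accuracy.

Known limitations: voxels are simulated independently (no spatial
structure, so no meaningful searchlight analogue); the HRF used by the
generator and the boxcar window used by the estimator are deliberately
similar but not identical, so recovered betas are proportional, not equal,
to planted pattern amplitudes; and the cross-factor joint non-uniformity
noted above places a small ceiling on how cleanly "the other factor stays
at chance" can hold when planted amplitudes are made very large.
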