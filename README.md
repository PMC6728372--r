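# allodecode

Simulation and multivariate decoding of allocentric direction signals in
fMRI region-of-interest time series.

## The problem

In spatial navigation, *allocentric boundary direction* — whether an
environment boundary lies to the North, South, East or West of you,
regardless of where you stand or face — is a core ingredient of positional
coding, and is hypothesised to be represented separately from the
allocentric direction of a *goal*. Testing this with multivoxel pattern
analysis (MVPA) requires a task design in which the two factors are
orthogonal, a per-trial estimate of the evoked response in each region of
interest (ROI), a cross-validated classifier of direction from voxel
patterns, and a group-level test of whether decoding accuracy beats the
4-class chance level of 25%.

`allodecode` implements that entire chain as tested, reusable R code, and
pairs it with a synthetic BOLD generator that plants direction-specific
multivoxel patterns with known amplitude into realistic nuisance (slow
drift, motion-coupled signal, AR(1) + white noise). Because ground truth
is known, the package can demonstrate end to end that the pipeline
recovers planted signals and stays at chance when none exist. It is aimed
at researchers who want a scrutable reference implementation of this
analysis style, or a simulation harness for power and validity checks.

## What is inside

| stage | functions |
|---|---|
| design | `build_environment()`, `enumerate_paths()`, `build_trial_table()`, `verify_balance()`, `enumerate_jrd()`, `occupancy_fraction()` |
| simulation | `generate_condition_patterns()`, `generate_motion()`, `simulate_roi_timeseries()`, `simulate_cohort()` |
| nuisance + betas | `friston24_expansion()`, `highpass()`, `residualize()`, `estimate_trial_betas()` |
| decoding | `order_and_average()`, `nested_cv_accuracy()` |
| group stats | `bootstrap_means()`, `bca_interval()`, `monte_carlo_p()`, `bonferroni_alpha()` |
| orchestration | `default_config()`, `run_pipeline()`, `save_config()`/`load_config()` |

The model at the core: per trial *t* with boundary direction *b(t)* and
goal direction *g(t)*, the simulated ROI signal is

    Y = Σ_t [ p_boundary(b(t)) + p_goal(g(t)) ] x_t' + drift + motion coupling + ε,

where the `p(·)` are equal-norm voxel patterns separated by a planted
amplitude and `x_t` is the trial's HRF-convolved regressor. The estimator
inverts this with a 128-s cosine high-pass, the 24-regressor motion
confound model, and an additive per-trial GLM (own boxcar at 6–12 s post
onset + all-other-trials boxcar + intercept); condition-ordered averaging
across the 3 runs yields 96 samples (24 per direction) which a nested
cross-validated linear SVC (C grid 1–10³) classifies. Group inference uses
a BCa bootstrap CI and a shifted-to-chance Monte Carlo test,
p = (exceedances + 1)/(B + 1) with B = 10,000.

## Worked example

An 8-participant cohort with a boundary signal (amplitude 0.35) planted in
a 100-voxel ROI and no goal signal:

```r
library(allodecode)

cfg <- default_config(
  n_participants = 8,
  rois = list(roi_config("posterior_roi", n_voxels = 100,
                         amp_boundary = 0.35, amp_goal = 0)),
  seed = 42L)
res <- run_pipeline(cfg)
print(res)
#> Pipeline result (8 participants)
#>   posterior_roi  allo_boundary mean 0.498  p = 9.999e-05
#>   posterior_roi  allo_goal     mean 0.241  p = 0.6818

round(res$accuracies$posterior_roi$allo_boundary, 3)
#> [1] 0.526 0.421 0.456 0.561 0.456 0.596 0.439 0.526

print(res$group$posterior_roi$allo_boundary)
#> Group decoding: mean 0.4978 (chance 0.25), n = 8
#>   BCa 95% CI [0.4583, 0.5395], Monte Carlo p = 9.999e-05 (B = 10000)
```

The planted factor decodes at ~0.50 against a chance level of 0.25 and the
Monte Carlo p is at its floor of 1/10,001 (none of the 10,000 shifted-null
bootstrap means reached the observed mean), while the unplanted goal
factor stays at chance (0.241, p = 0.68). A full run writes `report.json`
(accuracies, p-values, CIs, null histograms) when `out_dir` is given, and
`inst/scripts/run_pipeline.R` wraps the same call for shell use.

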