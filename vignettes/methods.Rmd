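---
title: "Models and methods behind denovofmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind denovofmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denovofmri)
```

This vignette is the package's own account of what it computes and why the
design is the way it is: the task model, the synthetic-data generator and
what it does and does not emulate, the GLM conventions, the numerical
choices, and the known limitations.

## The task model

A participant controls a cursor through an affine map `r = A s + r0` from a
14-channel glove posture `s` to 2-D screen coordinates. The rows of `A` are
the top two principal components of the sensor covariance during free
movement, so the cursor tracks the two dominant directions of finger motion.
Three conventions make the fit deterministic and usable, none of which is
forced by the mathematics:

* **Sign**: each principal component is flipped so its largest-magnitude
  loading is positive (eigenvectors are sign-ambiguous).
* **Scale** (`fit_mapping(scale = "grid")`, the default): each row is scaled
  so ±2 SD of its latent PC score spans the 5-unit grid axis. This makes the
  calibration workspace cover the grid, which is the practical requirement
  for the task; `scale = "unit"` keeps unit-norm principal axes instead.
* **Offset**: `r0` places the calibration-mean posture at the grid center.

Continuous cursor space is `[0, 5] × [0, 5]` grid units with row 1 at the
top; cell `(i, j)` is the half-open square `[j−1, j) × [i−1, i)`, so a
boundary position belongs to exactly one cell and the cell number
`k = 5i + j − 5` bijects the grid. The per-trial success rate is the
fraction of trajectory samples whose containing cell is the target cell;
off-grid samples count as failures. Because the statistic is a per-sample
proportion, it is invariant to the sampling rate for piecewise-constant
trajectories.

Reachability of all 25 cells is checked by mapping a dense 101×101 lattice
of the 2-D latent preimage of the sensor working box through the mapping and
marking the cells hit. Transition paths between targets count distinct
ordered pairs of *distinct* consecutive targets, including the wrap-around
pair, since blocks repeat back to back; each printed 12-trial sequence
traverses all `4 × 3 = 12` ordered pairs of its four targets.

One documented ambiguity: the calibration slice is described in the source
protocol both as the last two and the last three movement blocks. The
generator tags calibration frames with block numbers and `fit_mapping()`
consumes whatever slice it is given, so either convention is a one-line
filter; the default calibration uses two blocks.

## The synthetic learner

The generator's job is to produce behavior with the statistical structure
the analysis assumes — block-wise improvement, higher success with visual
feedback, residual trial-to-trial variability — not to model human motor
learning mechanistically. The learner is a noisy proportional controller in
the cursor plane: at 50 Hz, each step moves `gain/rate` of the remaining
distance to the target center and adds Gaussian noise scaled so the
stationary positional SD around the target is `σ_b`. That SD decays across
blocks,

```
σ_b = σ_∞ + (σ_0 − σ_∞) exp(−λ (b − 1)),
```

is multiplied by `off_noise_mult` in cursor-off blocks (no online feedback
means noisier control and *more* movement — which is exactly the confound
the boxcar regressors are there to absorb), and is jittered per trial by a
log-normal factor (`trial_jitter`) modeling attentional fluctuation. The
jitter matters: without it, late-session and test-run success rates sit at a
near-constant ceiling, the mean-centered parametric regressor for the test
condition degenerates toward zero, and its coefficient becomes
unestimable — which is not what real, perpetually variable performance looks
like.

Defaults, chosen once as plausible for this task and then frozen:
`σ_0 = 0.8` grid units (early success ≈ 0.2 with feedback), `σ_∞ = 0.22`
(late success ≈ 0.8), `λ = 0.08` per block, `off_noise_mult = 3`,
`gain = 3 /s`, `trial_jitter = 0.35`. Groups additionally draw each
subject's `σ_0`, `σ_∞`, `λ` and multiplier from log-normal jitter
(`subject_sd = 0.25`) around these values; without between-subject
heterogeneity, group F statistics are implausibly large because the only
variance left is sampling noise. At n = 24 the simulated group reproduces
the qualitative behavioral pattern: strong stage and condition main effects
and a stage×condition interaction (feedback accelerates learning), with
off-block-only improvement still present.

What the learner does **not** emulate: trajectory curvature constraints
("move as straight as possible"), memory-based strategies, fatigue, or any
model-based/model-free distinction — only the emergent learning-curve shape
is calibrated.

## The BOLD phantom

`make_phantom()` builds an ellipsoidal brain with disjoint labeled regions:
bilateral putamen and caudate (each crossing the Y = 0 plane), a midline
vmPFC blob, bilateral V5 and M1. The affine places Y = 0 *between* slices,
so anterior/posterior assignment of voxel centers is unambiguous. Each
striatal structure is split at Y = 0 into coupling subregions that partition
it exactly; the 1-voxel-gap convention belongs to the ROI analysis (below),
not to the ground-truth coupling, so every striatal voxel carries signal.

`simulate_bold()` inverts the analysis model exactly: region signal is the
sum of condition boxcars (amplitudes per region and condition, in percent of
the 100-unit baseline) and `γ[region, condition]` times the mean-centered
success-rate pulse train, both convolved with the same HRF the design module
uses. On top of that: polynomial drift in the same discrete orthogonal basis
the design includes (coefficients `c(6, 4, 3, 2)` on the unit-norm degree
1–4 columns), stationary AR(1) noise (ρ = 0.3) with SD 1 percent per voxel,
and per-run motion traces — a small-step random walk plus planted sustained
steps of 0.8 mm whose frames are exactly the set the 0.4-mm censoring rule
flags. Because the simulated signal lies in the span of the fitted design,
the noiseless limit recovers `γ` to numerical precision; that identity is a
test, and any model-mismatch bug breaks it loudly.

Coupling defaults (percent signal per unit mean-centered success rate) place
the strongest positive couplings in the striatum (anterior > posterior,
caudate stronger in the cursor-off condition), a cursor-on/test-only vmPFC
coupling, a negative cursor-on/test V5 coupling (more cursor motion with
worse performance), and boxcar-only coupling in M1 plus the posterior
putamen for the Move/Stop localizer. Magnitudes (0.9–2.6) were chosen once
so that group-level recovery and the striatal ROC selectivity property are
comfortably achievable at the default noise level, and are stored with every
simulated dataset as the ground-truth record.

What the phantom does **not** emulate: anatomical shapes, spatial noise
correlation (smoothing-induced or physiological), hemodynamic nonlinearity,
susceptibility dropout, or motion-induced signal artifacts (motion traces
feed the censoring and nuisance logic only). Passing tests therefore show
the *estimator* is correct and well-calibrated under the assumed noise
model, not that real data meet those assumptions.

## GLM design conventions

* **HRF**: difference of two gamma densities, peak delay 6 s, undershoot
  delay 16 s, unit dispersions, peak:undershoot 6, 32-s kernel, normalized
  to unit peak — the standard double-gamma shape; all parameters are
  configurable in `hrf_spec()`.
* **Convolution grid**: 0.1-s fine grid, FFT convolution, then left-edge
  sampling at the TR. Pulse amplitudes are `a_k − ā` at the trial *offset*
  (end of the 4-s window).
* **Centering scope**: `ā` is the mean success rate across all trials of
  the same condition in the whole session (passed to per-run builders via
  `abar`), so a condition's regressor is centered consistently across runs;
  per-run centering is available by omitting `abar`.
* **Conditions**: the split design gives each condition present in a run a
  parametric and a boxcar column; test-run trials get their own columns
  rather than being pooled with cursor-on, matching how the conditions are
  reported separately. The single-parametric mode pools all trials around
  one mean for the overall-sensitivity analysis. In Move/Stop mode only the
  Move boxcar enters; Stop is the implicit baseline, so the Move > Stop
  contrast is the Move coefficient against zero.
* **Drift**: five discretely orthogonal polynomial columns (constant plus
  `stats::poly` degrees 1–4). Continuous Legendre polynomials evaluated at
  scan times are only approximately orthogonal in the sample inner product;
  the discretely orthogonalised basis spans the same quartic trends and
  makes the Gram matrix exactly diagonal.
* **Censoring**: frame displacement is the Euclidean norm of the
  first difference of the six motion parameters, rotations in degrees
  treated as mm-equivalent (the common enorm convention for a 0.4-mm
  threshold); the first frame is never flagged. Censored volumes are dropped
  as rows, which the tests verify is identical to explicit row deletion.

## Estimation and inference

`fit_subject()` concatenates all runs: task columns are shared across runs
by label, drift and motion nuisances are block-diagonal per run, and the fit
is ordinary least squares per voxel via one QR decomposition (no
prewhitening — with AR(1) noise OLS is unbiased but not minimum-variance,
a documented simplification). Rank deficiency after censoring, empty
conditions, and all-zero retained task columns raise informative errors.

`group_ttest()` computes the one-sample t against zero per voxel and maps it
through the t CDF to a z score (`z = Φ⁻¹(F_t(t))`, computed on the log scale
so large |t| does not saturate prematurely), preserving sign and rank order.
Zero-variance voxels with nonzero mean get `|z| = 40` and a QC flag.

`cluster_calibrate()` simulates white Gaussian fields, smooths them to the
requested FWHM by FFT (wrap-around is negligible for masks away from the box
edge at the FWHMs used), standardizes within the mask, thresholds two-sided
at the voxel-wise p, and records the largest 6-face-connected component per
iteration; the critical size is the `1 − α` order-statistic quantile of that
null distribution. The published critical sizes for any particular study are
mask- and smoothness-specific, so the tests check the calibration's
monotonicity properties (in FWHM and in α) rather than any fixed voxel
count.

## ROC selectivity and ROI statistics

For thresholds θ from −8 to 8 in steps of 0.5, sensitivity is the fraction
of target-mask voxels with `z ≥ θ` and specificity the fraction of
non-target brain voxels with `z < θ` (predicted-positive is the
high-z side). The curve is anchored at (0,0) and (1,1) in
(1 − specificity, sensitivity) space and AUC is the trapezoidal area; on a
continuous threshold grid this converges to the Mann–Whitney statistic of
target versus non-target z values, which the tests use as an independent
oracle at tolerance matching the 0.5-step discretization. Both the
split-condition z maps and the pooled single-regressor map can feed the ROC,
since either analysis mode produces a `group_stat`.

The anterior/posterior ROI split classifies voxel centers by world Y through
the affine: anterior `Y > g/2`, posterior `Y < −g/2`, with `g` = gap width
(default one voxel size); the excluded band is exactly the gap and the three
parts partition the parent mask. With the phantom's between-slice Y = 0
plane, the default gap excludes the two slices adjacent to the boundary,
which is the conservative reading of a "1-voxel gap" around a plane that
does not coincide with any slice.

ROI condition contrasts are two-sided paired t tests on per-subject ROI mean
β's, reported uncorrected (multiple-testing correction across ROI contrasts
is deliberately not applied, matching how such ROI bars are conventionally
reported). The 2×2 repeated-measures ANOVA uses the within-subject
decomposition via `aov()` error strata and reports partial
η² = SS_effect/(SS_effect + SS_error). All factors here have two levels, so
sphericity holds trivially and the Greenhouse–Geisser ε is reported as an
inert 1. Missing trials fail loudly rather than being imputed — incomplete
subjects should be excluded upstream, not patched.

The test-versus-late-on stability comparison uses unweighted per-stage means
(6 on-blocks versus 12 test blocks), the simplest defensible choice where
weighting is unspecified.

## Problem sizes and numerical tolerances

The routine test suite and the study-scale acceptance checks use a 24³
phantom (≈ 4,600 brain voxels), 20 simulated subjects for parameter recovery
and selectivity, 24 subjects for the behavioral ANOVA, 500 Monte-Carlo
iterations for cluster calibration, and 2,000 replicates for the paired-t
type-I check — sizes at which every stochastic property tested has
comfortable margin while a full run stays in the minutes range on one core.
The phantom constructor enforces a 24³ minimum so all regions fit disjointly;
32³ is the default for interactive use. Exact identities (noiseless
recovery, censoring-equals-deletion, normal-equation equivalence) are tested
at 1e−8; orthogonality and serialization round trips at 1e−10 or tighter.

## Known limitations

* OLS without prewhitening under AR(1) noise: unbiased β's, mildly
  optimistic per-subject standard errors; group inference rests on
  between-subject variance and is unaffected to first order.
* The phantom's noise is spatially independent, so cluster-extent thresholds
  calibrated at a nominal FWHM are conservative relative to data whose
  smoothness exceeds it, and the ROC separability is cleaner than real maps.
* The learner is phenomenological; its parameters have behavioral, not
  neural, interpretations, and the planted couplings are constants rather
  than learning-dependent quantities.
* Real anatomical atlases, MRI acquisition, and preprocessing (despiking,
  slice timing, registration, warping, smoothing, intensity scaling) are out
  of scope: the simulator emits data as if already preprocessed, and the
  analysis consumes any conforming NIfTI + TSV dataset.
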