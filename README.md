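# denovofmri

Simulation and analysis of performance-coupled fMRI during continuous *de
novo* visuomotor learning.

In the task this package models, a participant wearing a 14-channel data
glove learns to steer an on-screen cursor through an arbitrary linear
hand-to-cursor mapping

```
r = A s + r0,        A ∈ R^{2×14},  r0 ∈ R^2,
```

where `s` is the glove posture and the rows of `A` are the first two
principal components of free-movement calibration data. Targets appear on a
5×5 grid (cell number `k = 5i + j − 5`) in fixed 12-trial sequences; the
per-trial success rate `a_k` is the fraction of the 4-s trial the cursor
spends inside the target cell. Sessions alternate cursor-on and cursor-off
feedback blocks over four learning runs, followed by two cursor-on test runs
with the alternate target set.

The imaging question is where BOLD activity scales with that success rate.
The package implements the full analysis chain:

* **Task geometry** (`fit_mapping()`, `cell_index()`, `target_sequence()`,
  `success_rate()`, `check_reachability()`) — PCA mapping fit, grid
  indexing, and the behavioral statistic.
* **Synthetic data** (`simulate_calibration()`, `simulate_session()`,
  `make_phantom()`, `simulate_bold()`) — a noisy-proportional-controller
  learner that reproduces the block-wise learning pattern, and 4D BOLD
  phantoms whose labeled regions (bilateral putamen and caudate split
  anterior/posterior, vmPFC, V5, M1) carry known condition-specific
  couplings `γ` to the mean-centered success rate, plus polynomial drift,
  AR(1) noise, and motion traces with planted super-threshold spikes.
* **GLM design** (`hrf()`, `parametric_regressor()`, `boxcar_regressor()`,
  `drift_regressors()`, `censor_mask()`, `build_design()`) — the parametric
  regressor `r(t) = Σ_k h(t − τ_k)(a_k − ā)` with a double-gamma HRF,
  per-condition boxcars absorbing the movement confound, quartic polynomial
  drift, six motion nuisances, and 0.4-mm frame censoring.
* **Estimation and inference** (`fit_subject()`, `group_ttest()`,
  `cluster_calibrate()`, `threshold_map()`) — voxel-wise OLS over
  concatenated censored runs with run-wise nuisances, one-sample group t
  maps converted to z, and Monte-Carlo cluster-extent calibration on
  smoothed Gaussian null fields.
* **Selectivity and ROI statistics** (`roc_curve()`, `roi_mean()`,
  `split_anterior_posterior()`, `condition_contrast()`) — ROC of the group
  z map against an anatomical striatum mask over thresholds −8…8 in steps
  of 0.5 (AUC 1 = perfect spatial selectivity, 0.5 = chance), ROI mean-β
  extraction with the anterior (Y > 0) / posterior (Y < 0) split and a
  1-voxel gap.
* **Behavioral statistics** (`block_curve()`, `early_late_split()`,
  `paired_t_two_sided()`, `rm_anova_2way()`) — block learning curves,
  early/late stage splits, two-sided paired t, and 2×2 repeated-measures
  ANOVA with partial η².

Everything is tibble-first: behavior tables, design matrices, ROC curves and
ROI summaries pipe through dplyr, results have `tidy()`/`glance()` methods,
and `autoplot()` draws learning curves and ROC curves. Volumetric data are
plain arrays read and written as NIfTI-1 via RNifti. `simulate_study()` /
`analyze_study()` run the whole pipeline against an on-disk dataset layout.

## Worked example

```r
library(denovofmri)

# 24 simulated learners: stage x feedback-condition ANOVA on block success
beh   <- simulate_behavior_group(session_config(n_subjects = 24), seed = 1)
curve <- block_curve(beh)
tidy(rm_anova_2way(stage_condition_table(curve),
                   "mean_rate", "subject", "stage", "condition"))
#>   effect            df1   df2     F        p partial_eta_sq
#> 1 stage               1    23 214.  3.93e-13          0.903
#> 2 condition           1    23 524.  2.50e-17          0.958
#> 3 stage:condition     1    23  48.5 4.27e- 7          0.678
autoplot(curve)   # block-wise group learning curve with SEM ribbons

# a small imaging group on a 24^3 phantom: GLM, group z map, striatal ROC
ph  <- make_phantom(dim = c(24, 24, 24))
grp <- simulate_and_fit_group(6, ph, seed = 1)
gs  <- group_ttest(grp$fits, label = "param_on", mask = ph$masks$brain)
glance(roc_curve(gs, ph$masks$striatum, ph$masks$brain))
#>     auc n_target n_nontarget n_thresholds
#> 1 0.997      158        4482           33

# anterior putamen responds more under cursor-on than cursor-off feedback
roi <- roi_summary(grp$fits, ph$masks[c("putamen_l_ant", "putamen_l_post")])
condition_contrast(roi, "on", "off", region = "putamen_l_ant")
#>   estimate     t    df         p degenerate region        contrast
#> 1    0.412  11.2     5 0.0000979 FALSE      putamen_l_ant on > off
```

The ANOVA reproduces the qualitative learning pattern (strong stage and
condition main effects and their interaction: visual feedback speeds
learning), the ROC AUC near 1 says the group z map singles out the striatum
almost perfectly, and the ROI contrast shows the planted feedback-condition
difference in the anterior putamen.

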