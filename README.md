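# effortdm

Simulation and analysis of **effort-based decision making for reward** in
developmental cohorts — the paradigm in which a participant decides, trial
by trial, whether a reward (4, 8 or 12 points) is worth a required grip
force (20%, 50% or 80% of their maximum voluntary contraction), 72 trials
over three runs. The package is built for studies comparing children with a
documented maltreatment history (MT) to matched non-maltreated peers (NMT)
and asking whether effort-related activity in the anterior cingulate cortex
(ACC) marks latent vulnerability to later internalizing symptoms.

Everything is data-frame-in / tibble-out, pipes cleanly, and fitted objects
have `tidy()`, `glance()` and `autoplot()`/`plot_*()` methods.

## What it implements

**Choice model.** Acceptance of offer (R, E) follows a five-parameter
lapse-logistic model per subject:

```
p(accept) = nu/2 + (1 - nu) * sigmoid(b0 + br * R/12 + be1 * E + be2 * E^2)
```

with intercept `b0`, linear reward sensitivity `br`, linear and quadratic
effort sensitivities `be1`, `be2`, and lapse probability `nu` (random
responding through inattention). `fit_hierarchical()` estimates all
subjects jointly by hierarchical Bayesian MCMC (JAGS) with weakly
informative hyperpriors; `compare_models()` ranks a nested model family by
WAIC-based expected log predictive density with standard errors.
`subjective_modulators()` and `cost_benefit_weights()` turn fitted
parameters into the per-trial parametric modulators used in first-level
fMRI models.

**ROI GLM.** `build_design_matrix()` makes HRF-convolved (double-gamma)
design matrices with mean-centered, non-orthogonalized modulators;
`fit_first_level()` extracts per-subject subjective-reward and
subjective-effort contrast estimates from ROI-average signals;
`sphere_voxel_set()` / `write_roi_mask()` build 6-mm spherical ROIs (ACC at
MNI (0, 14, 46), bilateral striatum) on a 2-mm grid.

**Group statistics.** Pooled and covariate-adjusted group tests with
Cohen's d (`d = t * sqrt(1/n1 + 1/n2)`), Benjamini–Hochberg FDR correction,
mixed-design reward × effort × group ANOVA with Greenhouse–Geisser
correction and partial eta squared, Pearson correlation tests, Fisher
r-to-z comparison of independent correlations, and exact two-sample t-test
power via the noncentral t.

**Longitudinal models.** OLS prediction of follow-up internalizing symptoms
from baseline symptoms + ACC effort beta + covariates within the MT group,
the two-group ACC × group interaction model, standardized coefficients,
last-entry ΔR² per predictor, and added-variable (partial regression)
plots.

**Synthetic cohorts.** `cohort_config()` + `generate_cohort()` produce
seeded, bit-reproducible cohorts — task schedules, choices, ROI contrasts
with a configurable standardized ACC group effect (default d = 0.52) and an
ACC–effort-sensitivity coupling within MT (target r = 0.44), and a
longitudinal symptom panel — so the whole pipeline can be exercised and
calibrated end to end. `run_pipeline()` chains every stage and writes
provenance-hashed CSV/JSON outputs; a thin CLI lives at
`inst/cli/effortdm.R`.

## Worked example

```r
library(effortdm)

# Self-contained design computations
ttest_power(37, 33, d = 0.75, alpha = 0.05)
#> [1] 0.8703089                      # >= 80% power at the study's n

fisher_z_compare(0.439, 36, -0.12, 33)
#> # A tibble: 1 x 2
#>       z      p
#> 1  2.35 0.0190                     # the two ACC~effort-sensitivity r's differ

gg_dfs(0.655, df1 = 2, df2 = 2 * 67)
#> # A tibble: 1 x 2
#>   df1_gg df2_gg
#> 1   1.31   87.8                    # GG-corrected dfs for a 3-level factor

# A small end-to-end synthetic study
cfg <- pipeline_config(
  master_seed = 2026,
  cohort  = list(n_mt = 14, n_nmt = 14),
  models  = c("intercept", "full"),
  sampler = list(n_chains = 2, n_adapt = 400, n_warmup = 400, n_iter = 600))
report <- run_pipeline(cfg, out_dir = "effortdm_out", quiet = TRUE)
report
#> <run_report> seed 2026 hash 58fe5f8e
#>   best model: full
#>   ACC effort group test: t(26) = -2.65, p = 0.013, d = -1.00
#>   MT follow-up model R^2 = 0.73

report$model_comparison
#> # A tibble: 2 x 6
#>   model       elpd    se p_eff elpd_diff se_diff
#> 1 full       -976.  24.4  49.4        0      0
#> 2 intercept -1171.  18.8  25.0      195.    18.4
```

The full lapse-logistic model beats the intercept-only model by ~195 ELPD
points (about 10 SEs) — the simulated cohort really does trade reward
against effort. The ACC effort-modulation betas recovered by the first-level
GLM separate the groups in the built-in direction (NMT above MT; the
negative t is MT − NMT), and within the MT group lower ACC activation
predicts more follow-up symptoms. At n = 14 + 14 the realized effect size
(d ≈ −1.0) is, as expected, a noisy draw around the generating d = 0.52.

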