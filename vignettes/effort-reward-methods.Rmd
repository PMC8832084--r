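---
title: "Modelling effort-based decision making for reward: methods and design choices"
author: "effortdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling effort-based decision making for reward}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

`effortdm` implements an analysis pipeline for a physical-effort
decision-making task used to study reward processing in children and
adolescents, including cohorts with documented maltreatment histories. On
each trial a participant sees an offer — a reward (4, 8 or 12 points) for a
required grip force (20%, 50% or 80% of their maximum voluntary contraction,
MVC) — and accepts or declines. The 3 × 3 factorial design is presented 8
times per cell, 72 trials over three runs. The scientific questions the
pipeline addresses are:

1. How do reward and effort levels shape the decision to exert effort
   (choice modelling)?
2. Does effort-related neural activity in pre-specified regions (anterior
   cingulate cortex, striatum) differ between maltreated (MT) and
   non-maltreated (NMT) groups (ROI GLM + group statistics)?
3. Does baseline ACC effort-related activity predict internalizing symptoms
   about 18 months later (longitudinal regression)?

Because raw data of this kind are not publicly deposited, the package ships
a first-class synthetic-cohort generator whose statistical structure mirrors
the study design, so the full pipeline can be exercised, tested and
power-analyzed end to end.

## The choice model

Each subject's probability of accepting offer $(R, E)$ is a lapse-logistic
mixture with five parameters:

$$
p(\text{accept}) \;=\; \frac{\nu}{2} + (1 - \nu)\,
\sigma\!\big(\beta_0 + \beta_r \tilde r + \beta_{e1} \tilde e +
\beta_{e2} \tilde e^2\big),
$$

where $\sigma$ is the logistic function, $\tilde r = R / 12 \in \{1/3, 2/3,
1\}$, $\tilde e = E \in \{0.2, 0.5, 0.8\}$ is the MVC fraction, and $\nu \in
[0, 1]$ is a lapse (noise) parameter: the probability of responding at
random through inattention, splitting equally between accept and decline.
The mixture bounds acceptance probabilities in $[\nu/2, 1 - \nu/2]$.

Two choices here were genuinely open and are fixed as package conventions:

* **How "noise" enters.** Randomness in responding could be modelled as an
  inverse temperature or as a lapse mixture. We adopt the lapse mixture —
  the standard "random responding due to inattention" formulation — because
  it keeps the sensitivities interpretable on the logit scale and yields a
  bounded, well-identified noise probability. Alternative members of the
  family can be expressed through `model_spec()`.
* **Input scaling.** Rewards are scaled by the maximum reward (so
  $\beta_r$ is the logit change from zero to maximal reward) and effort
  enters as the raw MVC fraction with its square. This makes parameter
  values comparable across implementations and keeps the quadratic term's
  units transparent.

The model family is a nested ladder (`choice_model_family()`):
intercept-only → + linear reward → + linear effort → + quadratic effort →
+ lapse. Excluded terms are fixed at zero.

## Hierarchical Bayesian estimation

`fit_hierarchical()` estimates subject-level parameters under partial
pooling: each parameter is drawn from a group-level normal distribution
(the lapse on the logit scale). Hyperpriors are weakly informative soft
constraints: group means $\sim \mathcal N(0, 5)$, group SDs $\sim$
Half-Normal(2.5), and the logit-lapse group mean $\sim \mathcal N(-3, 1.5)$,
which favours small lapse rates a priori. Sampling is by MCMC through JAGS
(4 chains, 1000 warmup + 1000 retained draws by default; every chain's RNG
is seeded from the sampler config, so fits are bit-reproducible).

Diagnostics are split-$\widehat R$ and effective sample size per free
parameter. JAGS is a Gibbs-family sampler, so there is no
divergent-transition count (an HMC concept); a fit whose maximum
$\widehat R$ exceeds 1.05 is returned with `converged = FALSE` and a
warning, never silently.

By default the hierarchy pools all subjects into a single population; group
differences are then assessed on the per-subject posterior means with
t-tests, matching how per-subject estimates are compared downstream.
Separate per-group hyperparameters are available with `by_group = TRUE`.

**Model comparison.** Fits are ranked by expected log predictive density
(ELPD). With no leave-one-out machinery available in the dependency set,
the ELPD is computed as WAIC from the pointwise log-likelihood (the widely
used approximation to leave-one-out cross-validation), with a standard
error from the pointwise contributions; pairwise differences between models
report the SE of the pointwise difference. `compare_models()` refuses fits
whose data fingerprints differ.

**A note on flat-prior sanity checks.** With near-flat hyperpriors a
single-subject posterior should agree with a penalized maximum-likelihood
fit of the same likelihood. That equivalence is only well-posed for the
concave members of the family: the full model's likelihood has a ridge
(as sensitivities grow, choices become deterministic and the lapse absorbs
all errors), and $\tilde e$ and $\tilde e^2$ over three effort levels are
nearly collinear ($r \approx 0.99$), leaving the flat-prior MLE
ill-conditioned in the $(\beta_{e1}, \beta_{e2})$ direction. The package's
equivalence test therefore uses the intercept + reward + linear-effort
member, where agreement holds to ~0.02 at 576 trials. This is also why the
hierarchical priors matter scientifically at 72 trials per subject:
recovery of the quadratic effort term and the lapse is imperfect by
construction.

## The synthetic cohort

`cohort_config()` fixes the study conditions; `generate_cohort()` composes
the pieces with sub-seeds derived deterministically from one master seed
(`derive_seed()`), so the same config always yields a bit-identical cohort.

Defaults and their rationale:

* **Group sizes** 37 MT / 33 NMT — the analyzed cohort sizes.
* **Choice parameters** drawn per subject from normal distributions with
  means $(\beta_0, \beta_r, \beta_{e1}, \beta_{e2},
  \text{logit}\,\nu) = (1.5, 2, -1, -3, -3)$ and SDs $(1, 1, 1.5, 2, 1)$,
  identical in both groups because no behavioural group differences were
  observed in this paradigm. The means give a mean acceptance rate near
  70% with acceptance rising in reward and falling (increasingly steeply)
  in effort — the qualitative fingerprint of this task family, in which
  quadratic effort discounting dominates.
* **Task timing**: decision phase jittered uniformly on 3–4.5 s, exertion
  fixed at 4 s, outcome jittered on 1.5–2.5 s. The inter-trial interval is
  fixed at 1 s — the simplest defensible timing model where the protocol is
  silent. Trial order is a seeded permutation of the fixed cell multiset;
  with 8 repetitions over 3 runs exact within-run balance is impossible
  (8 is not divisible by 3), so the generator balances within run whenever
  the repetition count divides the run count and otherwise guarantees
  overall balance with equal run lengths.
* **Exertion success** probabilities default to (0.95, 0.85, 0.75) by
  effort level; no group differences in success are built in. Points are
  never deducted.
* **Covariates**: age uniform on 10–16 years, sex Bernoulli (60% female),
  pubertal status ordinal 1–4 loosely tracking age, maltreatment severity
  ordinal 1–4 in the MT group and 0 in the NMT group by definition. These
  match the cohort's margins loosely; the exact joint distribution is
  plumbing, not substance.
* **ROI contrasts**: the ACC effort-modulation beta differs between groups
  by a configurable standardized effect, default $d = 0.52$ with NMT above
  MT; striatal betas and all reward-modulation betas carry no group
  difference. Within the MT group the ACC effort beta is coupled to the
  subject's linear effort sensitivity with target correlation 0.44.
  Subjects are standardized against the *population* (generator)
  parameters, not the realized sample, so betas remain independent across
  subjects and marginally $\mathcal N(\mu, \sigma^2)$ — this matters for
  the null calibration of downstream tests.
* **Symptom panel**: baseline internalizing symptoms are drawn from
  group-specific normals (MT 2.7 ± 2.2, NMT 1.7 ± 1.9, floored at 0);
  follow-up symptoms are linear in baseline symptoms (slope 0.6), the ACC
  effort beta (slope −1 in the MT group, 0 in the NMT group, so lower
  activation predicts more symptoms), small covariate effects, and Gaussian
  noise (SD 1.5).

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: no reaction-time process, no
force-trace time series (only per-trial mean force and success), no
temporal autocorrelation or motion artefacts in the ROI signals (white
noise by construction), no measurement model for the questionnaires, no
floor/ceiling effects in follow-up symptoms beyond the baseline floor, and
no missingness or dropout. Conclusions about estimator behaviour under
those features require real data or a richer generator.

## First-level fMRI model

`build_design_matrix()` constructs the subject-level GLM: three condition
regressors time-locked to the decision/choice phase (jittered 3–4.5 s),
effort exertion (4 s, accepted trials) and outcome (1.5–2.5 s, accepted
trials), each convolved with a canonical double-gamma HRF (peak delay 6 s,
undershoot delay 16 s, unit dispersions, peak:undershoot 6:1, 32 s support,
peak-normalized). Parametric modulators — subjective reward
$\beta_r \tilde r$, subjective effort
$\beta_{e1}\tilde e + \beta_{e2}\tilde e^2$ (from each subject's fitted
parameters), the cost-benefit weight $|\text{cell acceptance rate} - 0.5|$
on the decision phase, mean applied force on exertion, and points obtained
on outcome — are mean-centered within condition *before* convolution and
are **not** serially orthogonalized (the modern convention; orthogonalization
order would otherwise silently reassign shared variance). A constant
modulator centers to zero and is dropped with a warning; rank-deficient
designs are an error naming the collinear columns.

Conventions fixed where the protocol is silent: repetition time 2 s,
microtime resolution 0.1 s, runs concatenated at a 400 s offset. Synthetic
ROI-average signals are white-noise OLS problems by construction, so no
AR(1) model or motion regressors are included — a deliberate simplification
flagged here. ROI masks are spheres of 6 mm radius on a 2 mm grid
(voxel-center distance ≤ radius, inclusive boundary; 123 voxels at r = 6),
centered at the pre-specified peaks: ACC (0, 14, 46), right striatum
(22, 14, 6), left striatum (−14, 6, 10). Bilateral structures are combined
as the unweighted mean of left and right betas.

## Group statistics

* **Group tests.** The ROI comparisons use the pooled-variance (Student)
  t-test by default: the reported ROI dfs in this literature (67 at
  n = 69) imply plain t-tests, while covariates of no interest enter the
  second-level analyses elsewhere; `adjusted_group_test()` provides the
  covariate-adjusted variant and a Welch option sits behind a flag.
  Cohen's d is converted from t as $d = t\sqrt{1/n_1 + 1/n_2}$; printed
  effect sizes in this literature can differ from this conversion in the
  third decimal, so d is never compared tighter than ±0.01.
* **Mixed ANOVA.** Acceptance rates per subject × (3 reward × 3 effort)
  cell enter a two-group × two-within-factor ANOVA. Sums of squares and
  Greenhouse–Geisser $\varepsilon$ come from a multivariate linear model
  (`car::Anova`); the package assembles corrected dfs
  ($\varepsilon \cdot \text{df}$, error df convention $(N - g)(k - 1)$,
  which reproduces printed dfs such as 87.8 $= 0.655 \cdot 2 \cdot 67$ —
  the $(N-1)$ convention does not) and partial $\eta^2 =
  SS_\text{effect}/(SS_\text{effect} + SS_\text{error})$.
  $\varepsilon$ for a 3-level factor is bounded in $[1/2, 1]$.
* **Multiplicity.** Non-independent test families are corrected with the
  Benjamini–Hochberg step-up procedure (`bh_adjust()`).
* **Correlations.** Pearson r with the exact t-based test; independent
  correlations are compared with Fisher's r-to-z,
  $Z = (\text{atanh}\,r_1 - \text{atanh}\,r_2)\big/\sqrt{1/(n_1-3) +
  1/(n_2-3)}$.
* **Power.** Two-sample t-test power via the noncentral t distribution
  with $\text{ncp} = d\sqrt{n_1 n_2/(n_1+n_2)}$; at $n = 37 + 33$,
  $d = 0.75$, $\alpha = 0.05$ two-tailed this gives ≈ 0.87, consistent
  with "at least 80% power for d > 0.75".

## Longitudinal models

`fit_followup_regression()` predicts follow-up internalizing symptoms in
the MT group from baseline symptoms, the ACC effort beta, sex, age,
pubertal status and maltreatment severity, by OLS on complete cases (no
imputation). Standardized coefficients z-score all continuous variables and
leave binary predictors 0/1, so "β" is reproducible. The per-predictor
"part r²" is defined as the last-entry ΔR² (squared semipartial): the drop
in model R² when that predictor is removed — printed part-r² values in this
literature cannot be reproduced from printed t, df and R² by any standard
formula, so the two-fit definition is the package's defined behaviour, and
each ΔR² is verified against an explicit two-fit oracle. Note that squared
semipartials only partition R² when predictors are orthogonal; with
suppression their sum can exceed R², which is expected behaviour, not an
error. Degrees of freedom are always $n - p - 1$ computed from the data
actually supplied. The interaction model codes MT = 1, so the
group × ACC coefficient is the MT-minus-NMT slope difference.
`partial_regression_points()` returns added-variable-plot residuals whose
OLS slope equals the full-model coefficient (Frisch–Waugh–Lovell), which is
asserted in the tests at 1e-10.

## Reproducibility and problem sizes

Every stochastic function takes a seed; pipeline stages derive sub-seeds
from one master seed by hashing the stage name, so any stage can be rerun
independently and the whole pipeline is byte-identical across reruns of the
same config. All tables are written with a config-hash provenance header
and readers refuse to mix files from different configs.

The test suite and the acceptance script favour problem sizes that exercise
the methods at full fidelity while remaining quick to run: recovery checks
use cohorts of 40 subjects × 72 trials (averaging recovery correlations
over three replicate cohorts, since a single cohort's correlation at
n = 40 has a standard error near 0.13); model-comparison checks use 10
replicates of 20–30 subjects with single-chain reduced sampling;
effect-size convergence uses 10,000 subjects per group; null calibrations
use 1,000 replicate cohorts at the study's group sizes. The end-to-end
pipeline default runs the full 37 + 33 cohort with a reduced two-chain
sampler.

## Known limitations

* The lapse parameter is weakly identified at 72 trials per subject;
  its recovery correlation sits near the 0.3 boundary and group-level
  inferences about ν at this trial count should be treated with caution.
* Reward sensitivity is partially collinear with the intercept because
  scaled reward only spans $[1/3, 1]$; hierarchical pooling mitigates but
  does not remove this.
* WAIC approximates leave-one-out ELPD; for very influential observations
  PSIS-LOO would be preferable.
* The ROI stage models ROI-average signals, not voxelwise data; no
  whole-brain inference is provided.
* Gibbs sampling mixes slowly on the full lapse model; the defaults favour
  more iterations over reparameterization, and fits flag
  $\widehat R > 1.05$ rather than failing.
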