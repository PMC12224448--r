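---
title: "Latent heart-brain axes and mediation of the vascular risk-cognition association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent heart-brain axes and mediation of the vascular risk-cognition association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbaxis)
```

## The scientific question

Elevated vascular risk (hypertension, diabetes, hypercholesterolaemia,
smoking, adiposity) is reliably associated with poorer cognitive function
in middle and older age, but the mechanism is contested. The
structural-functional account holds that vascular risk drives adverse
cardiac remodelling, which compromises cerebral perfusion and damages
brain structure, which in turn lowers cognitive function. If that chain
is right, measures of heart and brain structure should *mediate* the
vascular risk-cognition association, heart mediators should associate
with brain mediators, and a joint heart-brain axis should be an
especially strong mediator.

`hbaxis` implements the full analysis that such a study needs — latent
variable construction, joint heart-brain axes, covariate-adjusted
associations, a propensity-matched native-unit contrast, and single /
parallel / sequential mediation with bootstrap inference — together with
a synthetic-cohort generator whose structural paths are known exactly,
so that every stage of the pipeline can be validated against closed-form
ground truth.

## The generative model

`synth_spec()` defines a standardized linear latent system. All latents
have unit variance; all loadings and path coefficients are standardized,
so a path of `-0.55` means one SD of the upstream latent moves the
downstream latent by 0.55 SD. The structural skeleton is

```
gVRF --a--> heart mediator --d--> brain mediator --b2--> g
   \________________b1 (heart mediator -> g)___________/
    \_______________c (direct path gVRF -> g)__________/
```

so the total standardized gVRF-g effect decomposes by path tracing as
`c + a*b1 + a*d*b2`, which `implied_effects()` returns and the test
suite uses as the oracle for mediation recovery. The defaults
(`a = -0.55`, `b1 = 0.078`, `d = 0.40`, `b2 = 0.02`, `c = 0.01`) imply a
total effect of `-0.037`, a small negative association of the size
typically reported for vascular risk and general cognitive ability, with
essentially all of it carried by the heart-mediator path — the
"complete mediation by latent myocardial intensity" pattern the package
is designed to detect.

Observable blocks are built from the latents:

* **VRF indicators** (8): three binary diagnoses generated by a
  liability-threshold model (liability = loading x gVRF + unique noise;
  diagnosis when the liability exceeds a cutpoint, so with no covariate
  effects the prevalence is `1 - pnorm(threshold)`), plus pack-years
  (left-censored at zero, so "ever smoked" has a controllable
  prevalence), systolic/diastolic blood pressure, BMI and
  waist-to-hip ratio on native scales. Default loadings span 0.30-0.75
  with adiposity strongest, the typical ordering for a general
  vascular-risk factor.
* **Cognitive tests** (4): verbal-numerical reasoning and prospective
  memory are linear; reaction time is stored as an exponentiated normal
  (so a natural-log transform restores a normal, negatively g-loaded
  score) and visual-memory errors are zero-inflated (point mass 0.3)
  and exponentiated, so the `log(x + 1)` transform is exercised
  non-trivially.
* **Heart and brain feature blocks**: each block latent carries a named
  standardized loading vector; features add unique noise
  (`sqrt(1 - lambda^2)`), age and sex effects per variable class, and
  body-surface-area (heart) or head-size (brain) confounder effects.
  Familiar features get native units (ventricular volumes in mL, grey
  matter in mm^3, FA/MD on tract scales, WMH exponentiated and
  right-skewed).

**Shared heart-brain axes.** A shared axis couples one heart latent to
one brain latent so that the *feature-level* canonical correlation
matches the requested target. Because latents are only measured through
noisy indicators, the best linear combination of a block correlates with
its latent at the factor-score determinacy
`rho = sqrt(lambda' Sigma^-1 lambda)`; the generator therefore inflates
the latent-level coupling to `r / (rho_heart * rho_brain)` and rejects
targets that would need a coupling of 1 or more. The default axes
(0.70, 0.45, 0.30) echo the magnitude ordering reported for empirical
heart-brain modes of population covariation.

What the generator deliberately does **not** emulate: real radiomics
marginal distributions and scanner artefacts, site/batch effects,
selection into imaging substudies, non-linear age trajectories, and
diagnosis ascertainment error. Passing tests therefore demonstrate that
the estimators recover the truth under a faithful linear-Gaussian
rendering of the analysis assumptions — not that those assumptions hold
in any particular cohort.

## Preparation

`transform_cognitive()` applies the skew transforms recorded in the data
dictionary (`ln` for reaction time, `ln1p` for visual memory) and logs
them in an append-only provenance trail that `replay_transforms()` can
verify. `aggregate_vrf_count()` counts six binary criteria — the three
diagnoses, ever smoking (pack-years > 0), BMI > 25, and high
waist-to-hip ratio (> 0.85 for females, > 0.90 for males) — with strict
inequalities at the printed cutoffs. `complete_case_filter()` drops
subjects with any missing required value, one role at a time, and
reports the attrition per step; no imputation is offered by design.
Z-scoring uses the n-1 denominator and returns its statistics so that
training-set scalings can be re-applied to new data.

## Latent models

* **Single-factor CFA** (`fit_cfa()`): maximum likelihood on the sample
  correlation matrix with the factor variance fixed at 1, so loadings
  are standardized and comparable across indicators. The optimizer is
  L-BFGS-B with analytic gradients of the ML discrepancy; uniquenesses
  are bounded below at 0.005 and a solution pinned there (a Heywood
  case) is clamped with a warning. Binary indicators are treated as
  continuous — a documented fidelity limitation; a categorical
  estimator is out of scope. Factor scores use the regression method
  `lambda' Sigma^-1 x`, which maximizes determinacy; the
  score-vs-truth correlation is bounded by
  `sqrt(lambda' Sigma^-1 lambda)` and the tests assert scores reach
  that bound to within 0.05.
* **PCA with cross-validated rank** (`fit_pca()`): unrotated components
  of the z-scored block. The rank is chosen by element-wise (Wold)
  cross-validation — delete a random fifth of the cells, impute them
  with rank-k EM-PCA, score held-out reconstruction MSE — with a
  one-standard-error rule preferring the smallest competitive rank.
  Subject-level CV cannot choose PCA rank (reconstruction error falls
  monotonically in k); element deletion is the standard fix. Rank 0
  (the column-mean model) competes too, so pure-noise blocks retain
  nothing.
* **CCA with permutation-calibrated retention** (`fit_cca()`): paired
  weight vectors from a Cholesky-whitened SVD of the cross-covariance;
  modes ranked by canonical correlation. Retention uses 5-fold
  subject-level CV: a mode is kept while its mean held-out correlation
  exceeds the 95th percentile of a 100-permutation null (held-out
  scores of one block shuffled across subjects), stopping at the first
  failure. A ridge of `1e-3 * mean(diag)` is added to a within-block
  covariance only when it is numerically singular. Note that retention
  answers "is there generalizable correlated variance", so on cohorts
  with shared age/sex effects more modes than the designed axes can be
  genuinely significant; the axis-recovery tests use effect-free
  cohorts for that reason.
* **Sign conventions**: every factor, component, and mode is oriented so
  its largest-magnitude loading/weight is positive (CCA flips both
  sides together to preserve the correlation); flips are recorded.
* **Deconfounding** (`deconfound()`): each latent score is replaced by
  its OLS residual on the confounders (intercept included) and
  re-standardized. The operation is a projection, hence idempotent;
  both raw and deconfounded variants of every downstream table are
  emitted by the pipeline.

## Associations, matching, mediation

`pairwise_latent_models()` fits every ordered pair of latents as
`dependent ~ independent + age + sex` (L latents give L(L-1) models; 19
latents give the familiar 342), reporting the standardized coefficient,
the additional R² beyond the covariates (operationalized as the R²
increment of the full over the covariate-only model, clipped at zero),
and BH-FDR q-values over the family. The FDR family is all records of
one command, not a global union across commands.

`estimate_propensity()` / `match_nearest()` / `paired_compare()`
implement the native-units contrast: logistic propensity for "4+ VRFs"
vs "no VRFs" given age, head size and body surface area; greedy 1:1
nearest-neighbour matching within exact sex strata, exposed processed in
descending propensity with ties broken by subject id (so the pair set is
row-order invariant), controls consumed without replacement, no caliper
by default (one can be supplied); then outcome-wise two-sample t-tests
with percent differences relative to the control mean. The unpaired
t-test is the default reading of "repeated t-tests between matched
groups"; a paired variant sits behind a flag.

`fit_mediation()` estimates all equations as seemingly-unrelated OLS
with a common covariate set (always age and sex, plus any extra
controls such as the other VRFs or BMI). With identical covariates the
difference in coefficients `c_total - c_prime` equals the summed
path-product indirect effects *exactly*, and the engine reports the
identity gap on every fit — the primary internal oracle (machine-zero
by construction, asserted `< 1e-10`). Percent mediated is
`100 (c_total - c_prime) / c_total`, flagged undefined rather than
infinite when the total effect is numerically zero; it legitimately
exceeds 100% when the direct effect flips sign, which is exactly the
complete-mediation regime. Inference is a percentile bootstrap
(subject-level resampling, default 1000 replicates, seed-reproducible);
percentile rather than BCa because it is the most reproducible choice,
with coverage verified by simulation in the test suite (93-97% at
nominal 95%). A mediator is called significant when the bootstrap CI
for its indirect effect excludes zero; q-values come from
normal-approximation bootstrap p-values, BH-adjusted within each
campaign. Complete mediation is declared when the direct effect's CI
covers zero while the indirect's excludes it.

Bootstrap replicates are computed from multinomial-weighted
cross-product matrices rather than resampled data frames, which makes a
replicate O(n·m²) and keeps the 500-replicate coverage simulation in the
test suite inside a few minutes on one core.

`run_campaign()` packages the four analyses: each imaging latent as sole
mediator of gVRF→g; a fixed heart mediator (latent myocardial
intensity, `heart_pc2` by default) with each brain latent as second
mediator in both parallel and sequential form; every VRF-exam pair
adjusted for the other VRFs; and every individual feature as sole
mediator. The sequential-vs-parallel contrast carries the signature the
structural-functional account predicts: when the heart→brain path is
modelled, the brain-specific indirect (`a2*b2`) collapses toward zero
while the heart-routed paths persist.

## Numerical choices and degenerate inputs

* Zero-variance columns are an error wherever a scale is needed, naming
  the column.
* Rank-deficient mediation designs are an error; bootstrap replicates
  that go singular are redrawn and counted, with >1% failures an error.
* CFA non-convergence raises an error carrying the gradient norm;
  Heywood cases are clamped at 0.005 with a warning.
* Collinear confounders are dropped with a warning and the retained set
  logged.
* Sample SDs use the n-1 denominator throughout.
* All randomness flows from explicit seeds (`withr::with_seed`); no
  global RNG state is consumed, and identical spec + seed reproduce
  byte-identical tables.

## Problem sizes used in the validation suite

The synthetic study conditions fix cohort sizes by what each property
needs: n = 20,000 for loading/covariance convergence and the
complete-mediation recovery scenario, n = 10,000 for canonical-axis
recovery, n = 5,000 for CFA loading recovery (the default cohort size),
n = 2,000 with 1,000 bootstrap replicates across 500 Monte-Carlo
replicates for bootstrap coverage, 400 replicates at n = 1,000 for the
size of the indirect-effect test, 50 cohorts for PCA rank selection,
and n = 8,000 for the matched contrast (which yields study-scale groups
of several hundred exposed subjects).

## Known limitations

* Binary indicators enter the CFA as continuous variables; tetrachoric
  or categorical-ML estimation is not implemented.
* Mediation models are linear with at most two ordered mediators; no
  causal sensitivity analyses (unmeasured confounding, E-values) and no
  longitudinal structure — the models quantify statistical, not causal,
  mediation.
* The percent-mediated statistic is intrinsically unstable when the
  total effect is small relative to its sampling error (its SD scales
  with `SE(c_prime)/|c_total|`); read it jointly with the CIs of the
  direct and indirect effects rather than in isolation.
* The generator's confounder interface is generic (head size, body
  surface area); study-specific imaging confounder lists are the
  user's responsibility.
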