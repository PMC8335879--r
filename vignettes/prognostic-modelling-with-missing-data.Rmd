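---
title: "Developing and validating a survival prognostic model when training covariates are missing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating a survival prognostic model when training covariates are missing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

`micoxpen` builds prognostic models for overall survival from clinical-trial
training data in which some candidate prognostic factors are missing for some
subjects. The motivating setting is newly diagnosed transplant-ineligible
multiple myeloma, where six routinely collected factors — age, WHO
performance status (0–4), lactate dehydrogenase (LDH), C-reactive protein
(CRP), the lymphocyte:white-cell ratio and ISS stage (I–III) — are candidate
predictors but only about two thirds of subjects have all six recorded.
Discarding incomplete subjects wastes most of the missing information and can
bias the model; the package instead multiply imputes the training covariates
and carries the imputation through every later stage: penalty selection,
model fitting, assessment, internal validation and risk-group derivation.

# The modelling pipeline

## Multiple imputation by chained equations

Missing covariates are imputed `m` times by chained equations
(`impute()`, `imputation_spec()`):

* continuous covariates: Bayesian linear regression followed by predictive
  mean matching (PMM). The regression parameters are *drawn* from their
  large-sample posterior (σ² from a scaled inverse-χ², β from its normal)
  rather than plugged in, so between-imputation variability is properly
  propagated into Rubin's rules. Each missing cell then receives the
  observed value of one of `donors = 5` subjects whose predicted mean is
  closest, so imputed values always lie in the observed support.
* ordinal covariates: a cumulative-logit proportional-odds model
  (`MASS::polr`) with a posterior draw of its parameters; the imputed level
  is *sampled* from the predicted category distribution, not the modal
  category, again to preserve variability.

Variables are visited from least to most missing (ties broken by schema
order). Each conditional model regresses its target on the other prognostic
factors, the auxiliary variable sex, the survival time in months and the
event indicator. Survival time in months (rather than the Nelson–Aalen
cumulative hazard, which is available via
`imputation_spec(survival_covariate = "nelson_aalen")`) is the default
outcome representation, a deliberate simplification. The randomised
treatment arm is excluded throughout: a treatment-specific model would limit
applicability, and the design assumes no strong treatment effect.

The number of imputations follows a pre-specified rule (`choose_m()`): 10 if
no covariate exceeds 25% missing, otherwise the percentage of incomplete
cases rounded up. The chained equations run for `iterations = 5` cycles
after a marginal-draw initialisation; 5 cycles and 5 donors are conventional
defaults, configurable because they are not dictated by the method.

## Standardisation and design matrix

Because the multivariable model penalises all coefficients equally,
continuous covariates are standardised *within each completed dataset* using
the mean and the **population** standard deviation (divisor *n*):
`x_s = (x − x̄)/σ`, `σ² = Σ(xᵢ − x̄)²/n` (`compute_standardization()`).
Pre-specified transformations (log for LDH, log(1+x) for CRP, chosen from
histogram review of skewness) are applied before imputation so that the
conditional models work on the analysis scale.

Ordinal covariates are **not** standardised. They enter as orthonormal
polynomial contrasts (`ordinal_contrasts()`, the `contr.poly` convention:
equally spaced scores, unit-length zero-sum columns), which already puts
them on a comparable scale and keeps the linear/quadratic terms
interpretable.

## Penalised fitting with one shared penalty

The multivariable model maximises the LASSO-penalised Cox partial
log-likelihood; computationally this is `glmnet`'s coordinate descent, so λ
is on glmnet's per-observation scale (the objective is ℓ(β)/n − λΣ|βᵢ|).
To stabilise variable selection across imputations a *single* penalty λ\* is
used everywhere (`lambda_star()`):

1. a 100-point log-spaced λ sequence is generated from the first imputed
   dataset (down to 0.001·λ_max);
2. the same sequence — and the same event-stratified 10-fold split, since
   the subjects are the same rows in every completed dataset — is
   cross-validated in each imputed dataset, minimising the partial-likelihood
   deviance;
3. λ\* is the arithmetic mean of the m optima.

Penalised coefficients have no usable model-based standard errors, so
`bootstrap_se()` refits `B_se = 100` resamples at the fixed λ\* within each
imputed dataset and takes the coefficient SD.

## Rubin's rules with a fixed denominator

Coefficients and bootstrap SEs are pooled by Rubin's rules (`pool()`,
`pool_model()`): pooled estimate = mean, total variance
T = W + (1 + 1/m)B, normal-reference 95% CIs. When the LASSO drops a
variable in only some imputations, that variable contributes **zero**
estimate and **zero** bootstrap variance for those imputations and the
denominator stays m — the pooled coefficient of a variable selected j of m
times is (sum of its j estimates)/m. This represents that penalisation
occurred in some but not all completed datasets. Variables never selected
are reported as excluded. Whether a dropped variable should instead
contribute its resample SD is not determined by the method; the zero
convention is the package default.

# Assessment

*Proportional hazards.* Unscaled ("weighted") Schoenfeld residuals are
regressed on event time, covariate by covariate, in each imputed dataset
(`ph_check()`); non-proportionality is flagged at the 5% level in any
imputation. The unscaled version is used deliberately: the scaled version
requires inverting a variance matrix that may be singular when it comes from
bootstrap resampling of a penalised model.

*Calibration.* In each imputed dataset the fitted model's predicted survival
probabilities at 60 days and 1 year (Breslow baseline ×
exp(prognostic index)) are split into deciles; the group prediction is the
median, the group observation the Kaplan–Meier estimate with Greenwood 95%
CI (`calibration()`). Calibration is judged graphically, plus a summary
slope: OLS of predicted (response) on observed (regressor) over the ten
group points, pooled across imputations by the simple mean
(`calibration_slope()`). No CI accompanies the slope — ten points per
regression make interval estimates unreliable.

*Discrimination.* The prognostic-separation D-statistic (`d_statistic()`):
subjects are ranked by prognostic index, assigned scaled rankits by Bloom's
approximation z(i) = √(π/8)·Φ⁻¹((i − 3/8)/(n + ¼)), and survival is
regressed on the rankits in a Cox model; D is the slope, interpretable as
the log hazard ratio between prognostic halves. D depends on the PI only
through ranks, so it is invariant to monotone transformations, and — unlike
the C-statistic — it pools cleanly by Rubin's rules (`combined_d()`). Tied
PIs receive mid-rankits (the rankit evaluated at the average rank), a
deterministic, permutation-invariant convention. Uno's
censoring-robust C at both horizons (`uno_c()`, IPCW weights 1/Ĝ(t−)²) is
reported as a familiar companion, summarised across imputations by median
and IQR because its normality under Rubin pooling is doubtful.

# Validation

## Internal: bootstrap-then-impute optimism correction

`internal_validate()` repeats, B times: (I) resample n subjects with
replacement from the *incomplete* data; (II) rerun the whole pipeline on
the resample, including imputation and penalty selection; (III) pool into a
sample model and sample performance; (IV) apply the sample model's pooled
coefficients to the m imputed datasets of the original run; (V) pool into
the internal-validation performance; (VI) optimism = sample −
internal-validation. Corrected performance = apparent − mean optimism, an
identity the report asserts. Resampling before imputing, rather than
bootstrapping completed datasets, makes the imputation uncertainty part of
what the optimism estimate sees.

Two resolutions of genuinely open details: in step IV the original imputed
datasets keep their **original** standardisation (the sample model travels
only with its pooled coefficients — re-standardising the original data with
sample-run parameters would change the quantity being validated); and for
the calibration-slope measure the sample model also carries its pooled
Breslow baseline (the mean of its per-imputation baselines), since predicted
probabilities need one. Bootstrap coefficient SEs are *not* recomputed
inside replicates: neither D nor the slope uses them, only pooled point
estimates travel to step IV. Replicates that fail (event-free resamples,
degenerate fits, an all-zero model) are redrawn up to five times, then
skipped and counted in the report.

The default is B = 100; the package's own test suite and reproduction
script use scaled-down runs (B = 10–15 with m = 3–10) chosen to keep a
complete nested re-imputation loop — the point being validated — while
remaining quick to execute.

## External: complete cases first, imputation as sensitivity

`external_validate()` mirrors clinical use: only test subjects with every
*retained model variable* recorded are eligible; the training
transformations and the Rubin-pooled training standardisation constants are
applied; the PI uses the pooled coefficients; D, Uno's C and calibration are
computed against the pooled training baseline. A sensitivity analysis
(`external_validate_imputed()`) instead imputes the test set m = 10 times
with the same imputation model structure, applies the single pooled model in
each completed copy and Rubin-combines.

# Risk groups

The per-subject PI is averaged over the m (model, completed-dataset) pairs
into a combined PI (`pool_prognostic_index()`); its training-set tertiles
(type-7 quantiles, boundary subjects to the lower group) trichotomise both
cohorts into low/medium/high (`derive_groups()`), with Kaplan–Meier curves
by group (`km_by_group()`). The exact tertile convention is a documented
choice — several conventions give near-identical splits — and externally
published cutpoints can be supplied directly via the `cutpoints` argument.

# The synthetic-data generator

Real myeloma trial data are not redistributable, so `generate_trial()`
produces seeded cohorts with known truth. It emulates: the six covariate
marginals (normal age; categorical WHO PS and ISS; log-normal LDH and CRP;
beta L:W) with mild Gaussian-copula dependence between disease-severity
markers; exponential proportional-hazards survival driven by a known
coefficient vector on the transformed/standardised scale; independent
dropout plus staggered administrative censoring; and MAR missingness whose
per-variable logits depend on age, sex, survival time and event status, with
a shared latent "labs not done" factor so multi-variable missingness
patterns arise. The defaults were calibrated once to the training-cohort
study conditions — roughly 68% complete cases with LDH the most-missing
covariate (~22%), ~38% deaths at analysis, and a true prognostic separation
(D = √(8/π)·SD(PI)) near 0.84 — and are not adjusted per run.

What the generator does **not** emulate: myeloma biology, treatment effects,
real covariate covariance beyond the mild copula, non-proportional hazards,
or informative censoring. Tests passing on this generator therefore
demonstrate the *procedure* (unbiased recovery of generating coefficients,
nominal CI coverage, correct optimism arithmetic, calibrated PH-test size),
not performance guarantees on any real cohort.

# Numerical choices and degenerate inputs

* Ties in the Cox partial likelihood: Efron's approximation for unpenalised
  fits (Breslow available by flag); the Breslow estimator for the baseline
  cumulative hazard at fixed coefficients.
* glmnet convergence threshold 1e-10; a decreasing λ path ending at the
  target penalty is always supplied (path-wise fits are more stable than
  cold single-λ calls); single-column designs are padded with a null column
  glmnet requires, which can never be selected.
* The imputation regression draw adds a relative ridge (1e-5 of the mean
  diagonal) before inversion for numerical stability.
* Constant covariate columns refuse standardisation; all-tied PIs refuse a
  D-statistic; event-free data refuse any fit; groups whose follow-up ends
  (censored) before a calibration horizon are reported unavailable rather
  than extrapolated; horizons beyond the last event time extrapolate the
  survival curve flat, with a warning.
* All randomness flows from one root seed through named child streams
  (imputation, CV folds, bootstrap, simulation), so identical seeds replay
  every artifact bit-for-bit and components can be replayed in isolation.

# Known limitations

* The calibration slope is sensitive to model misspecification with only
  ten group points and carries no interval estimate; it supplements, never
  replaces, the graphical decile comparison.
* PMM cannot extrapolate outside the observed support; with heavy
  missingness in the tails it understates spread.
* The proportional-odds imputation model can fail under perfect separation
  in very small or very sparse resamples; such validation replicates are
  redrawn and, if persistent, skipped and reported.
* The package fits LASSO penalties only — no elastic net or ridge — and no
  time-varying coefficients; a flagged PH violation is a signal to move to
  a more flexible model, not something the package resolves.
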