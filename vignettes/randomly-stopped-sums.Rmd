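---
title: "Modeling randomly stopped sums: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling randomly stopped sums: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Many behavioural quantities are totals of a random number of non-negative
components: total gaze duration is the sum of individual fixation durations
over a random number of fixations; total deliberation time is the sum of
per-item inspection times over a random number of inspected items. Writing
`S_j = Z_1j + ... + Z_{N_j j}` for subject `j`, the package models three
linked quantities:

* the **frequency** `N_j`, a count with a log-link linear predictor
  `log E[N_j] = sum_k alpha_k x_kj`. Over-dispersion is the norm in such
  counts, so the working family is the negative binomial, stored internally
  in an (event probability `pi`, scale `phi`) parameterization with mean
  `theta = phi pi / (1 - pi)` and variance `omega^2 = phi pi / (1 - pi)^2`;
  converters to the (mean, size) convention are provided. Gamma-mixed and
  log-normal-mixed Poisson variants cover the same ground in the Bayesian
  formulation.
* the **magnitudes** `Z_ij`, positive values modeled on the log scale by a
  life distribution: gamma, log-normal, exponential, or inverse Gaussian.
* the **sums** `S_j` themselves, via a log-link GLM.

The central structural fact is log-link coefficient additivity: when all
three models use the log link and share a predictor, the sums-model
coefficient for that predictor is the sum of its frequency and magnitude
coefficients, `omega_k = alpha_k + beta_k`
(`predict_sums_coefficients()`). Two families of sums distributions have
exact conditional forms: gamma magnitudes `gamma(rho, s)` give
`S | N = n ~ gamma(n rho, s)`, and inverse Gaussian magnitudes
`IG(theta, kappa)` give `IG(n theta, n^2 kappa)`
(`conditional_sum_law()`). Log-normal magnitudes have no closed-form sum;
the "LN model" treats the sums as approximately log-normal, an
approximation with good support in the severity-modeling literature. The
marginal distribution of `S` mixes the n-fold convolutions over the count
distribution and has no closed form, so the package approximates it by
direct simulation (`simulate_sums()`); alternatives such as Panjer
recursion or Fourier convolution are deliberately out of scope.

## Estimation

Two estimators are provided.

**Simulation estimator.** `simulate_sums()` executes the three-step loop
(draw counts, draw magnitudes, sum) many times; 10,000–20,000 runs give
stable summaries. `bootstrap_sums_glm()` is a parametric bootstrap: each
replicate simulates every subject's sum from its group's specifications and
fits the sums GLM (LN: linear model on `log S`; GG: gamma GLM with log
link), accumulating coefficient draws, their means, medians, and 95%
percentile intervals. The specifications stay fixed at the supplied values
across replicates; refitting the frequency/magnitude models inside each
replicate would propagate their estimation error twice. Subjects drawing a
zero count are dropped from that replicate's fit (a zero sum has no log);
they are retained in frequency fits. Replicates with degenerate fits are
skipped and counted.

**Bayesian hierarchical estimator.** `build_model()` + `run_mcmc()` fit the
three layers jointly via JAGS. The frequency layer is a gamma-mixed
Poisson: `N_u ~ Poisson(lambda_u)`, `lambda_u ~ gamma(q, q / exp(eta_u))`
with `eta_u = X alpha`. The magnitude layer places a normal prior
`mu_u ~ N(ups_u, sigma_ups^2)` on the unit-level log location, with
`ups_u = beta_0k + Y beta` (one intercept per round in three-level data,
absorbing the random-coefficient variation). For the GG family the
magnitudes are `gamma(q_m, q_m / exp(mu_u))` and the sums layer is
`gamma(lambda_u q_m, lambda_u q_m / exp(muS_u))` with
`muS_u = mu_u + log(lambda_u)` — an identity that holds exactly in every
draw, so the sums coefficients are derived as `omega = alpha + beta`. For
the LN family the magnitudes and sums are log-normal, and the sums layer
has its own coefficients and free variance `sigma_s^2`, because the sum of
log-normals is not log-normal and the approximation error must go
somewhere. Observation-level predictors can be added to the magnitude layer
(`extend_with_observation_predictors()`), entering the sums layer through
the per-subject predictor sums.

"Uninformative" priors are made concrete as Normal(0, sd 100) on all
regression coefficients and Gamma(0.01, 0.01) on the shapes and on the
precisions of all variance components — standard diffuse BUGS-style
choices. Defaults are 2 chains, 5,000 burn-in, 10,000 kept draws;
convergence is gated on split-free Gelman–Rubin R-hat with a warning above
1.05. DIC is computed per layer from the monitored draws as
`Dbar + pD` with `pD = Dbar - D(posterior means)`, so the frequency,
magnitude, and sums models can be compared simultaneously.
`posterior_predict()` returns case-level posterior-mean frequencies,
magnitude means, and sums, incorporating the unit random effects
(`lambda_u`, `mu_u`); for the GG family these reproduce observed sums
almost perfectly (squared correlations above 0.99 on synthetic data), while
the LN sums layer, being fixed-effects only, predicts at the design-cell
level.

## Frequentist fitting choices

`fit_frequency_glm()` wraps a log-link Poisson or negative binomial GLM
(`MASS::glm.nb`, dispersion by ML jointly with the coefficients), and
reports the Pearson dispersion statistic as an over-dispersion diagnostic.

`fit_magnitude_model()` treats the **subject (or cell) as the analysis
unit** and models the per-unit mean magnitude: the LN family is a linear
model on the log of the per-unit means, the gamma family a gamma GLM on the
means. Modeling the means — rather than the per-observation values or the
per-unit mean of logs — matches the way the magnitude layer feeds the sums
(`S_j = n_j * mean_j`) and is what the package's own power study
calibrates against; an observation-level random-intercept engine (lme4) is
available as an opt-in alternative (`engine = "mixed"`), and agrees with
the subject-level fit within joint uncertainty on well-specified data.
Random intercepts only are modeled by default; random slopes are left to
the mixed engine, since the worked analyses need only the intercept
variation.

All Wald tests use the normal reference distribution (`z`), matching the
convention of count-GLM summaries. This is a real choice: with ~50
subject-level units a `t` reference would give Type I error rates at 0.050,
while the `z` reference gives the mild small-sample inflation (~0.056 at 25
per condition, decaying with sample size) that the package's Type-I-error
tables exhibit.

## The power study engine

`power_scenario()` + `run_scenario()` implement a two-condition design with
equal per-condition sample sizes. The calibrated baselines are negative
binomial counts with `pi = 0.5`, `phi = 10` (mean 10, variance 20) and
magnitudes with natural mean ~1000 and SD ~500 — log-normal(6.81, 0.447)
or gamma(shape 4, scale 250) — values typical of human response times in
milliseconds. These baselines are fixed study conditions, not tuning knobs.

Effect sizes are in baseline SD units and are operationalized as an
**additive shift of the natural-scale mean** by `d` baseline SDs with the
family's secondary parameter held fixed (`apply_effect()`): the negative
binomial holds `phi` and re-solves `pi`; the log-normal holds `sigma_log`
and re-solves `mu_log`; the gamma holds its shape and rescales. A
multiplicative (log-scale) shift is the main alternative reading of
"SD units"; the additive mapping is recorded in every CLI manifest so
tables are auditable against alternatives. Under it, a negative shift moves
a larger log-scale distance than the equal positive shift
(`|log(1 - d c)| > log(1 + d c)`), which is what produces the greater power
for negative effects. One consequence worth flagging: in
opposite-direction pairs the net log effect is larger when the *magnitude*
takes the negative role, so those cells are the most sensitive to the
mapping convention of any in the grid.

Per replicate the engine fits the frequency negative binomial, the
magnitude model on the per-subject means, and the sums model, and records
two-sided Wald significance of the condition coefficient at 0.05. For
speed, the two-group fits use closed-form equivalents of the GLMs
(coefficients are log group means; the negative binomial size is profiled
out with `MASS::theta.ml`; standard errors come from the Fisher
information). The test suite verifies these against `glm.nb`/`glm` to
numerical accuracy, so the fast path is an implementation detail, not a
model change. Replicates with a degenerate group (zero mean count) are
excluded and counted.

## The synthetic-data generator

`generate_fixture()` realizes the hierarchical generative model: counts are
gamma-mixed Poisson (marginally negative binomial at the baseline
parameters), magnitudes gamma or log-normal with a log-link linear
predictor, optional between-unit location noise `sigma_upsilon`, and
two- or three-level structure with per-round intercepts. Its defaults are
exactly the calibrated baselines above. What it deliberately does not
emulate: autocorrelation within subjects, heteroscedastic magnitude
variance, heavy-tailed contamination, and missingness — so green recovery
tests certify the estimators under the stated model, not robustness to
those violations. Subjects drawing a zero count contribute no rows, which
is also how real long-format data arrive (a subject absent from the
magnitude table has no observed magnitudes); at the baseline parameters
`P(N = 0) = 0.5^10 ~ 0.001`.

## Numerical choices and degenerate inputs

* Counts of zero are legal draws; their handling (retained in frequency
  fits, dropped from magnitude/sums fits) lives in the consuming modules.
* The negative binomial size estimator falls back to the Poisson limit
  (size 1e6) when a sample is under-dispersed and the ML estimate
  diverges.
* Gamma shape ML uses a Newton iteration on the profile score with a
  moment-based start; the inverse Gaussian sampler is the
  Michael–Schucany–Haas transformation.
* Bootstrap intervals are percentile intervals at 95%; simulation quantiles
  are the natural reading of a simulation-based interval.
* Skewness in `coefficient_pathology()` is the adjusted Fisher–Pearson
  sample skewness; outliers are draws beyond 3 IQRs from the median.
* Seeds: every stochastic entry point takes a seed, restores the caller's
  RNG state, and the CLI records a drawn seed rather than running silently
  unseeded.

## Problem sizes used in the checks

The package's own validation runs at deliberately reduced scale chosen to
exercise every code path with tight Monte Carlo control: power cells at
2,000–4,000 replicates (the table-reproduction script uses 10,000),
moment identities at 1e6 draws, and hierarchical coverage at 50
replications per configuration of two-level (60 subjects) and three-level
(40 subjects × 3 rounds) fixtures with short chains. Coverage is pooled
over the frequency and magnitude effect coefficients with a 90% gate on a
95% interval.

## Known limitations

* The LN sums layer omits unit-level random effects, so its case-level
  predictions are design-cell means; use the GG family when case-level
  sums prediction matters.
* Per-round intercepts together with round-level covariates are not
  jointly identified (the intercepts span all round variation); supply one
  or the other in three-level designs.
* The gamma-case Type I inflation of the sums test is not reproduced by
  this engine: at the calibrated parameters the simulated sums
  distributions under gamma and log-normal magnitudes are nearly
  indistinguishable (matched first two moments; conditional log-scale
  variances 0.025 vs 0.020 at the mean count), and the measured sums
  Type I error is ~0.053 in both cases at 10,000 replicates.
* Opposite-direction effect cells depend strongly on the effect-mapping
  convention (see above) and should be read with that caveat.
* In the same-direction grid, the cell where the sums model outpowers both
  constituent models (frequency effect 0.5, magnitude effect 0.2) does so
  by a very small margin under this engine (~0.003 at 25 per condition);
  treat that ordering as a tendency, not a testable effect at practical
  replicate counts.
* The observation-level extension's sums term aggregates per-subject
  predictor sums, which is an approximation: for data where the predictor
  acts multiplicatively on each magnitude, the sums layer implies a
  smaller slope than the magnitude layer, and the joint posterior settles
  between the two. Read `eta_w` as a detection parameter rather than an
  unbiased effect size.
* Autocorrelation and heteroscedasticity submodels are out of scope.
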