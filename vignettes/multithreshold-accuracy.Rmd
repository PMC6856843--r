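---
title: "Modelling diagnostic accuracy across explicit test thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diagnostic accuracy across explicit test thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous diagnostic tests (a biomarker concentration, a ratio of
laboratory measurements) are dichotomised in practice at a threshold $C$:
results above $C$ are called positive. Sensitivity and specificity then
depend on $C$, and primary studies in a systematic review typically report
accuracy at one or several — different — thresholds. Conventional
meta-analysis either throws away all but one pair per study or analyses
each threshold stratum separately, producing summary estimates that need
not even decrease with increasing threshold. **dtathresh** instead fits a
single model to all reported threshold-count data from every study,
yielding pooled sensitivity and specificity at *every* threshold together
with credible and prediction intervals, a summary ROC curve, model
comparison by DIC, and optimal-threshold selection.

## Within-study model

Study $i$ reports, for its disease-free ($j = 1$, size $N_{i1}$) and
diseased ($j = 2$, size $N_{i2}$) groups, the number of patients $x_{ijt}$
with test result strictly greater than each threshold
$C_{i1} < \dots < C_{iT_i}$. The thresholds partition each group into
$T_i + 1$ ordered categories, so each group's counts follow a multinomial
distribution. We work with its binomial factorisation,

$$x_{ij1} \sim \mathrm{Bin}(N_{ij},\, pr_{ij1}), \qquad
  x_{ijt} \mid x_{ij,t-1} \sim
  \mathrm{Bin}\!\left(x_{ij,t-1},\, pr_{ijt}/pr_{ij,t-1}\right),$$

where $pr_{i1t}$ and $pr_{i2t}$ are the false and true positive rates at
$C_{it}$. Because the $pr_{ijt}$ decrease in $t$ by construction, every
conditional probability lies in $(0,1)$ with no explicit ordering
constraints, and $T_i = 1$ studies are handled by the same code as
multi-threshold ones. The factorised log-likelihood includes all binomial
coefficients, so it equals the direct multinomial log-pmf exactly — the
test suite asserts this equality to $10^{-9}$ against an independent
multinomial evaluation.

The rates are linked to threshold by assuming that some monotone
transformation $g(\cdot)$ of test results in each population follows a
logistic distribution with location $\mu_{ij}$ and scale $\sigma_{ij}$:

$$\mathrm{logit}(pr_{ijt}) = \frac{\mu_{ij} - g(C_{it})}{\sigma_{ij}}.$$

$g$ is the Box-Cox family $g(C) = (C^\lambda - 1)/\lambda$
($\log C$ at $\lambda = 0$). $\lambda = 1$ means symmetric logistic test
results; decreasing $\lambda$ means increasing right skew, with
$\lambda = 0$ the log-logistic case that suits most positive-valued
biomarkers. $\lambda$ can be fixed (`transform_spec("fixed", 0)`) or
estimated with a Uniform$(-3, 3)$ prior
(`transform_spec("estimated")`; a Uniform$(1, 10)$ sensitivity prior can
be requested via `prior =`).

## Between-study model

Across studies, $\mu_{ij}$ and $\log \sigma_{ij}$ are normal with means
$m_{\mu j}, m_{\sigma j}$ and between-study SDs
$\tau_{\mu j}, \tau_{\sigma j}$. Three correlation structures are
available:

* **independence** — four independent random-effect sets;
* **structured** — two free correlations: $\rho_\mu$ between the two
  locations and $\rho_{\mu\sigma}$ between each location and its own
  log-scale, all other correlations *induced* through these (implemented
  and sampled through the exact conditional decomposition);
* **full** — all six correlations of the quadrivariate normal free.

Study-level covariates may shift any subset of the four means,
$m + \alpha^{\prime} z_i$; covariates are mean-centered by default so the
$m$'s keep their interpretation at the average study. With the log
transform, a coefficient $\alpha$ on a location has a ratio
interpretation: a covariate change $\delta$ multiplies the mean test
result by $e^{\delta\alpha}$ (`covariate_ratio()`).

Default priors are weakly informative: Normal$(0, 10^2)$ on means and
coefficients, Uniform$(0, 5)$ on between-study SDs, Uniform$(-1, 1)$ on
free correlations.

## Fitting, and two parameterisation choices

Models are fitted by MCMC with JAGS (`fit_dta()`), defaulting to 4 chains
of 1000 warmup + 1000 retained iterations. Two choices deserve note:

* **Full structure via product-normal.** Inside the sampler the dense
  quadrivariate normal is parameterised as four sequential conditional
  regressions (unit-lower-triangular coefficients $b$, conditional SDs
  $\psi$). This is positive definite by construction, which a Gibbs
  sampler needs; the implied $\tau$'s and six $\rho$'s are derived from
  $(b, \psi)$ per draw and reported under the usual names. The induced
  priors on the correlations are therefore not exactly Uniform$(-1, 1)$;
  the R-level density and sampling functions (`ranef_logpdf()`,
  `sample_study_effects()`) use the dense covariance with an explicit
  positive-definiteness check, and the two routes are cross-checked in the
  tests.
* **Initial values.** Location means start at the centre of the
  transformed threshold range. With flat starting points far from the
  data, the $(\mu, \sigma)$ ridge of weakly identified studies (notably
  $T_i = 1$) mixes very slowly.

The Box-Cox parameter mixes slowly (it trades off against all four means
and scales), so `convergence_report()` lists $\lambda$ first: check its
effective sample size before anything else, and prefer long, thinned runs
when estimating it. Reproducibility is exact for a fixed seed and JAGS
version.

## Model comparison

`compute_dic()` reports $\bar D$ (posterior mean residual deviance over
the conditional binomial terms), $p_D = \bar D - D(\hat p)$ with the
plug-in evaluated at the posterior means of the conditional binomial
probabilities — the likelihood's direct parents, matching the convention
of the general-purpose Bayesian samplers this model class is usually run
in — and $\mathrm{DIC} = \bar D + p_D$. Negative $p_D$ is flagged, not
hidden. `cmd_compare()` assembles the comparison table across persisted
fits and refuses to compare fits whose data checksums differ.

## Summaries

`summary_curve()` evaluates, per posterior draw, the summary rates at the
means of the four random-effect sets,

$$\mathrm{logit}\,fpr(C) = \frac{m_{\mu 1} - g(C)}{\exp(m_{\sigma 1})},
\qquad
\mathrm{logit}\,tpr(C) = \frac{m_{\mu 2} - g(C)}{\exp(m_{\sigma 2})},$$

and summarises across draws. The headline point estimate is the
*posterior median of the curve*, which is equivariant under monotone
transformations; the curve evaluated at the posterior-median parameters
is also returned (`*_at_median` columns) since the two do not coincide
exactly. The default grid is 200 log-spaced points spanning the observed
threshold range; wider grids are allowed but flagged as extrapolated —
estimates at extreme thresholds with little data are the least stable
part of any such analysis. `prediction_curve()` draws one new study per
posterior draw from the fitted between-study law (structure-respecting)
and reports pointwise 95% prediction bands; these are pointwise, not
simultaneous, intervals. `youden_optimal()` maximises
$J_w = 2[w\,tpr + (1-w)(1-fpr)] - 1$, which reduces to the Youden index
$tpr - fpr$ at $w = 0.5$; raising $w$ (a rule-out test) moves the optimum
to lower thresholds. Ties resolve to the smallest threshold.

## The synthetic-data generator

`simulate_dta()` draws datasets from the model's own generative process,
and is the basis of the recovery tests. The default scenario emulates a
natriuretic-peptide-style review: 18 studies, 50-500 patients per group,
1-7 thresholds per study drawn from a common 12-rung log-spaced ladder
over 25-2000 units, log-logistic results
($m_\mu = (4.4, 6.2)$, $m_\sigma = (-0.1, -0.1)$,
$\tau_\mu = (0.6, 0.5)$, $\tau_\sigma = (0.25, 0.25)$, $\lambda = 0$).
Study-specific threshold sets mirror the way real reviews mix cutoffs;
optional missingness drops interior thresholds per study-group, so the
two groups of a study may report different sets. A second, individual-level
path (`simulate_individual()`) draws raw logistic results and counts
exceedances; the tests check the two paths agree in law.

What the generator does *not* emulate: data-driven "optimal-threshold"
selective reporting (a recognised source of bias in real reviews),
digitisation error from reading counts off published ROC plots, assay
mixtures, or imperfect reference standards. Passing recovery tests
therefore show the estimator is consistent with its own assumptions, not
that those assumptions hold in any given review.

## Numerical choices

* Box-Cox branches: $\log C$ for $|\lambda| < 10^{-8}$, the second-order
  expansion $\log C + \lambda (\log C)^2/2$ for $|\lambda| < 10^{-4}$,
  keeping the transform numerically continuous in $\lambda$.
* Thresholds must be strictly positive; zero or negative thresholds are
  an error, never silently shifted. Duplicated thresholds within a
  study-group are an error, never merged. Counts are of results
  *strictly greater than* the threshold; the $>$ / $\geq$ distinction is
  a documentation matter only (continuous results make it
  probability-zero) and is not configurable.
* Probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ before logs to
  guard against underflow at extreme thresholds.
* Non-positive-definite full-structure correlation matrices are rejected
  with an error, never repaired.
* Rounding in `dta_from_accuracy()` that breaks count monotonicity is an
  error for the caller to resolve: there is no principled way to decide
  which of two conflicting digitised values is right.

## Simulation sizes used in the test suite

The recovery checks run 10 replicates of 30 studies (500 per group, 5
thresholds) for hyperparameter and curve recovery, and 5 replicates each
of $\lambda = 0$ and $\lambda = 0.5$ truths at 40 studies with 1000 per
group for Box-Cox recovery, with 2 chains per fit and thinned runs for
the estimated-$\lambda$ fits. These sizes keep the full suite in the
minutes range on a single CPU while leaving the coverage targets
(≥ 80% of replicates per hyperparameter; truth curve inside the credible
band at ≥ 90% of grid points) clearly resolvable.

## Known limitations

* A single transformation $g$ is assumed common to both populations and
  all studies; per-group or per-study $\lambda$ is out of scope, as is a
  two-parameter (shifted) Box-Cox. Separate analyses per assay are the
  recommended route when measurements are not comparable.
* DIC is reported because it is the standard for this model family, with
  its known pathologies (negative $p_D$ is possible and flagged).
* Prediction intervals are pointwise.
* The `"full"` structure is weakly identified in typical review sizes;
  expect correlations to return near their priors unless the meta-analysis
  is large.
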