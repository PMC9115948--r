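---
title: "Latent-variable pathway analysis: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable pathway analysis: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathsem)
```

## The scientific question

Cohort studies of cognitive ageing repeatedly observe that people with
more education, more complex occupations, higher incomes, and more
active social and leisure lives perform better on cognitive tests late
in life.  The open question is *through what*: do these life-course
factors act on cognition by limiting measurable brain pathology —
cerebrovascular small vessel disease (SVD), Alzheimer-type amyloid/tau
pathology, neurodegeneration — or do they act directly, e.g. through
compensation and cognitive reserve, independently of pathology?

`pathsem` implements a two-stage latent-variable mediation analysis of
this question, together with a calibrated synthetic-cohort generator so
that every stage of the machinery can be validated against known ground
truth even though individual-level data from such cohorts are
access-restricted.

## Stage 1: graded response models for the exposures

The social and lifestyle measurements are ordinal items.  Two separate
unidimensional graded response models (GRM) summarize them:

* an early-to-midlife **social indicator** (SI) built from education
  level (4 categories), occupational complexity (3), and household
  income (7–8 categories), and
* a latelife **lifestyle indicator** (LI) built from physical activity
  (3), a leisure-activity quartile (4), and the 0–3 social network
  index (SNI).

For item $j$ with $K_j$ ordered categories, the GRM specifies
cumulative probabilities
$$P(Y_j \ge k \mid \theta) = \operatorname{logit}^{-1}\!\big(a_j(\theta - b_{j,k-1})\big),$$
with discrimination $a_j > 0$ and strictly ordered thresholds
$b_{j,1} < \dots < b_{j,K_j-1}$, and the trait prior $\theta \sim
N(0,1)$ for identification (all discriminations free).  `fit_grm()`
maximizes the marginal likelihood by EM: the E-step computes posterior
weights on a fixed 61-node Gauss–Hermite grid, the M-step refits each
item by quasi-Newton on its expected complete-data likelihood, with
thresholds parameterized as (first threshold, log-spacings) so the
order constraint is automatic.  We use the logistic link without the
1.7 scaling constant, the common GRM default.  Missing item responses
simply drop out of that participant's likelihood product.

Participant scores are expected-a-posteriori (EAP) means under the
N(0,1) prior, computed on the same quadrature grid and then
standardized to sample mean 0, SD 1.  Sixty-one nodes are far more than
needed: the test suite shows agreement with adaptive numerical
integration to better than $10^{-6}$ (in practice $\sim 10^{-9}$).

Model fit is assessed with **two-way margins**
(`two_way_margins()`): for every item pair and category pair, the
observed pairwise frequency is compared with the model-expected
frequency obtained by integrating the product of category
probabilities over the trait, and cells with $(O-E)^2/E > 4$ are
flagged — the classical rule-of-thumb cutoff, chosen because the
diagnostic itself has no canonical reference distribution.

## Stage 2: structural equation model, estimated by FIML

The second stage treats the standardized trait scores as observed
exposures (the two-step approach mirrors the motivating analysis; the
uncertainty of the scores is *not* propagated, a known limitation noted
below).  Four latent variables are measured:

| Latent | Indicators (after preprocessing) |
|---|---|
| SVD | log WMH/TIV, periventricular Fazekas, deep Fazekas |
| AD pathology | log CSF p-tau, CSF A$\beta_{42}$/A$\beta_{40}$ ratio, amyloid-PET SUVR (log, z within radioligand) |
| Neurodegeneration | −z(log hippocampus/TIV), −z(cortical thickness), −z(BPF), −z(FDG SUVR) |
| Cognition | verbal fluency, FCSRT free recall, −log TMT-B, Rey figure |

Each latent regresses on `si_score`, `li_score`, age, sex, and APOE-e4;
cognition additionally regresses on the three mediators; the mediator
residuals covary freely.  The model is estimated in RAM form: a
directed-path matrix $A$ (loadings and regressions), a symmetric
covariance matrix $S$, a mean vector $m$, and an observed-row filter
$F$, with implied moments
$$\Sigma(\theta) = F(I-A)^{-1}S(I-A)^{-\top}F^\top, \qquad
  \mu(\theta) = F(I-A)^{-1}m.$$

Missing data are handled by full-information maximum likelihood under
MAR: each participant contributes the multivariate-normal log density
of their observed subvector, with rows grouped by missingness pattern
for speed.  The exogenous predictors are modelled jointly with free
means/variances/covariances so that FIML also covers their missingness
(APOE status is itself incomplete in real cohorts).  The gradient of
the FIML log-likelihood is computed analytically via the RAM chain
rule and checked against numerical differentiation in the test suite;
optimization uses `nlminb` with up to three jittered restarts, and
standard errors come from the inverse observed information
(central-difference Hessian of the analytic gradient).

### Identification and standardization

Each latent is identified by fixing its first loading to 1
(marker-variable convention) with a free residual variance.  The AD
pathology latent is anchored on CSF p-tau rather than the
A$\beta_{42/40}$ ratio so that the marker convention orients it with
*higher = more pathology* (the ratio then loads negatively); with the
ratio as marker, every AD-related coefficient would flip sign relative
to the orientation in which such results are conventionally reported.

`standardize_solution()` defaults to **endogenous-side**
standardization: latent variables are scaled to unit implied SD, while
observed exogenous predictors keep their natural units.  A coefficient
for age is then "SD of outcome per year", and for a binary covariate
"SD of outcome per group jump" — the convention under which mediation
tables in this literature print covariate effects (an age effect of
0.05 per year alongside a sex effect of 0.6 would be impossible under
full standardization).  Full standardization is available with
`mode = "all"`.  Free covariances become residual correlations
(covariance over the product of residual SDs).  Delta-method standard
errors on the standardized scale come from the numerical Jacobian of
the standardization map applied to the estimate covariance.

### Fit indices

With $T = 2(\ell_{sat} - \ell_{model})$ against the FIML-saturated
model (estimated by an EM algorithm for the unstructured multivariate
normal with missing data) and $T_b$ for the independence baseline:
RMSEA $= \sqrt{\max(0, (T - df)/(df\,n))}$ with a confidence interval
by root-finding on the noncentral chi-square (90% by default,
configurable — some reports print 95%); CFI and TLI in their standard
forms; SRMR as the root mean square of standardized residual moments
between the FIML-saturated and model-implied covariances (the only
well-defined sample analogue when no complete-data sample covariance
exists).  A model with `df = 0` reports its indices as undefined.

## Effect decomposition

For exposure $X$, mediator $M$, outcome $Y$: the indirect effect is
the product $ab$ of the $X \to M$ and $M \to Y$ paths, with
delta-method variance $b^2 V_a + a^2 V_b + 2ab\,C_{ab}$ taken from the
joint covariance of the standardized estimates; the total effect is
the direct path plus the sum over mediators of the products, with the
delta gradient $(1, b_1, a_1, b_2, a_2, b_3, a_3)$.  By construction
`total = direct + sum(indirect)` holds exactly.  P-values use the
normal approximation on the delta SE; a parametric bootstrap
(`bootstrap_indirect_se()`) is available as a check — the delta method
is known to be slightly anticonservative for products, and the test
suite requires agreement within 10% in a regime with clearly non-null
paths.

## The synthetic-cohort generator

`sim_config()` + `simulate_cohort()` emulate a memory-clinic cohort at
the level of the *derived* measurement table (no images, assays, or
longitudinal visits are simulated):

* **Covariates.** Age $\sim N(70.9, 8.7^2)$ truncated to (50, 95);
  61.9% women; 28.3% APOE-e4 carriers — the margins of the reference
  cohort ([reference_cohort_margins()]).
* **Traits and items.** Two latent traits with correlation 0.3 (a
  moderate value chosen once: the two life-course constructs are
  related but distinct; no reference estimate is available).  Ordinal
  items are drawn from GRMs whose thresholds are calibrated so the
  *marginal* category frequencies match the reference margins at the
  default discriminations (1.3–1.8).  The 0–15 leisure count is
  drawn uniformly within the sampled quartile band, with a 0–2
  physical sub-count so the sensitivity variant has something to
  exclude; the SNI is the sum of three Bernoulli items driven by the
  lifestyle trait.
* **Structure.** The structural coefficients default to the reference
  standardized direct effects ([reference_path_estimates()]), so
  parameter-recovery tests target the realistic regime; mediator
  residual correlations default to the reference residual
  correlations.  Latent residual variances are *solved* so every
  latent has unit total variance, making generative coefficients
  directly comparable to endogenous-standardized estimates.  A
  configuration whose coefficients would require negative residual
  variance is rejected.
* **Indicators.** Analysis-scale indicators are exact linear
  measurements with unit variance (loadings 0.60–0.85, chosen as
  typical communalities for these modalities); the raw table then
  inverts the preprocessing transforms (e.g. WMH volume
  $= \mathrm{TIV}\cdot e^{-6.6 + 0.8 z}$, TMT-B
  $= e^{4.6 - 0.45 z}$ seconds), with realistic location/scale
  constants.  Cognitive scores are rounded and clipped to their test
  ranges; Fazekas scores are kept continuous severity values rather
  than integers — the estimation treats them as continuous either way.
* **Missingness.** Whole modality blocks (CSF panel jointly;
  each PET) go missing with probability
  $\operatorname{logit}^{-1}(\alpha + s\,z_{age} + \tfrac{s}{2}
  \mathrm{female})$, where $\alpha$ is calibrated by root-finding so
  the realized marginal rate equals the target (defaults: CSF 82%,
  amyloid-PET 72%, FDG-PET 43% missing), and $s$ defaults to 0.4.
  Because the probability depends only on fully observed covariates,
  the mechanism is MAR by construction, and the test suite verifies
  that missingness is conditionally independent of the latent truth.
  Item-level MCAR missingness uses the reference footnote rates
  (e.g. income 13.6%, physical activity 10.9%, APOE 5.5%).
* **Seeding.** One master seed; each stage (covariates, traits, items,
  latents, indicators, missingness) uses a deterministic substream, so
  cohorts are byte-identical given the config.

What the generator deliberately does **not** emulate: non-normal and
heteroscedastic biomarker errors, site/scanner batch effects, selection
into PET/LP beyond age and sex, informative (MNAR) missingness,
integer-valued ordinal biomarker scales, and longitudinal structure.
Passing recovery tests on these cohorts therefore demonstrates the
*estimator machinery* is correct under its stated assumptions; it
cannot demonstrate robustness to the violations real data exhibit.

## Numerical choices

* GRM EM stops when the relative marginal log-likelihood change falls
  below $10^{-8}$ (cap 500 iterations); the final numerical gradient
  norm is reported on the model object.
* SEM optimization treats a gradient max-norm below
  $\max(10^{-5},\ 10^{-6}(1+|\ell|))$ as converged — an absolute
  cutoff is meaningless when $|\ell|$ ranges from $10^2$ to $10^5$.
  Non-positive-definite implied covariances are rejected as
  near-infinite objective values rather than crashing; Heywood cases
  (negative residual variances) produce a warning, not an error.
* Start values come from the FIML-saturated moments: exogenous moments
  and intercepts exactly, loadings by a triad estimate of the latent
  variance with a proportionality fallback, regressions at zero.
* Ties in the reduced-score quartiling of the `no_physical_leisure`
  variant use type-1 (left-continuous) sample quantiles.

## Sensitivity variants

`run_pipeline(..., variant = "no_sni")` drops the social network index
from the lifestyle GRM (motivated by its low correlation with the
other lifestyle items); `variant = "no_physical_leisure"` removes the
two physical leisure items from the leisure count before quartiling.
Since only the aggregate 0–15 count exists in the cohort table, the
generator emits the physical sub-count separately and the variant
re-quartiles the reduced 0–13 score at its own sample quartiles — the
published quartile cut-points are defined only for the full score.

## Problem sizes used in validation

The test suite exercises: GRM bias on the default calibrated banks
over 20 replicates of $n = 5000$; SEM coefficient recovery and CI
coverage over 50 replicates of $n = 2000$ (complete data, analysis
scale); chi-square calibration over 150 replicates of a small
one-factor model; FIML-vs-moment-ML agreement to $10^{-4}$ at
$n = 500$; MCAR unbiasedness over 25 replicates at $n = 800$ with 30%
missingness; and a 1000-replicate parametric bootstrap of an indirect
effect at $n = 500$.  These sizes were chosen to give tight Monte
Carlo error on a single CPU.

## Known limitations

* Two-step estimation: EAP scores are shrunken estimates of the
  traits, so exposure paths estimated from them are mildly attenuated
  relative to a hypothetical joint model — visible in the full-pipeline
  results as direct effects a few percent below the generative values,
  exactly as in the motivating two-step design.
* Ordinal indicators (Fazekas 0–3) are treated as continuous under ML;
  no polychoric/WLSMV estimation is provided.
* The delta method for products is first-order; for very small
  indirect effects its CI can undercover slightly (the bootstrap is
  the fallback).
* No multigroup, longitudinal, or MNAR extensions.
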