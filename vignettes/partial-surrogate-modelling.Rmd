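---
title: "Risk scores from partial surrogate outcomes: models, defaults, and design choices"
author: "surromix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk scores from partial surrogate outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surromix)
```

## The problem

Clinical risk scores are often trained on a *surrogate* outcome `S` — a
quantity that is cheap and quick to measure — rather than on the *target*
outcome `T` that actually matters clinically, because `T` arrives too late
or too rarely to support model development. The canonical example this
package is built around is perioperative acute kidney injury: the surrogate
is the maximum serum-creatinine change over the first two postoperative
days, and the target is the decline in estimated glomerular filtration rate
90 days after surgery (eGFR90), on a mean-0, SD-50 scale.

A surrogate can be *partial*: informative about the target in one
subpopulation and pure noise in another. Physiologically, patients whose
injury exceeds their renal functional reserve (subpopulation **V**) show a
creatinine response that tracks injury, while patients whose reserve
absorbs the injury (subpopulation **I**) show only nonspecific creatinine
fluctuation. Membership is latent. Training a single pooled regression on
such a mixture attenuates every coefficient and can badly mislead both
inference and risk ordering — and, worse, the usual practice of selecting
the model that best predicts the *surrogate* will systematically prefer
the pooled model even when its ordering of the *target* is inferior.

## The model

Write `Z` for the `n x p` covariate matrix. The package's core estimator,
`mixlm()`, fits the K-component mixture of Gaussian linear regressions

$$ f(s \mid z) \;=\; \sum_{k=1}^{K} \pi_k \,
   \phi\!\left(s;\; z^\top\beta_k,\; \sigma_k^2\right), $$

with *unconstrained* component variances, by maximum likelihood through
EM. The E-step converts the current parameters into posterior membership
probabilities (responsibilities)

$$ \tau_{ik} \;=\;
   \frac{\pi_k\,\phi(s_i; z_i^\top\beta_k, \sigma_k^2)}
        {\sum_j \pi_j\,\phi(s_i; z_i^\top\beta_j, \sigma_j^2)}, $$

and the M-step refits each component by responsibility-weighted least
squares, with `pi_k` updated to the mean responsibility. The observed-data
log-likelihood is non-decreasing across iterations; the test suite asserts
this at tolerance 1e-8 on every fit it makes.

Two risk scores are then compared against the target:

* **linear** — the prediction of the pooled single-component fit;
* **mixture_V** — the linear predictor of the single component identified
  *post hoc* as the informative one, evaluated for *all* subjects.

The informative component is the one with the largest mean absolute slope
(on standardized covariates); no identifiability constraint is imposed
inside EM, mirroring the post hoc identification the procedure is meant to
formalize. When the top two components are within 10% relative of each
other, a diagnostic warning flags the selection as fragile.

Discrimination is judged by measures of pure ordering only — AUC for the
dichotomized target and Spearman's rho for the continuous one — never by
calibration-sensitive measures: a model trained on a surrogate has no
reason to be calibrated against the target, only (one hopes) similarly
ordered. The minimal requirement for any score `R` is the concordance
criterion `P(R_i < R_j | T_i < T_j) > 1/2`, estimated in
`concordance_probability()` by pairwise (Somers-type) enumeration, with an
`O(n log n)` path through the standard concordance machinery for large
`n`; the two paths agree exactly, ties included.

## What the synthetic generator emulates

The clinical cohort the method was developed on (4737 cardiac-surgery
patients) is not publicly deposited, so the package ships a generator
that reproduces its *statistical structure* rather than its records:

* **Covariates.** Ten predictors — eight continuous (standardized) and two
  binary with marginal proportions 0.373 (diabetes) and 0.066 (emergency
  surgery) — with exchangeable latent-Gaussian correlation 0.2. The
  published analysis does not state the covariate joint distribution; an
  exchangeable structure is the simplest dependence that is not
  independence, and marginal proportions are taken from the published
  cohort table.
* **Membership.** Bernoulli draws with `P(V) = 728/4737`, the modal share
  of the informative subpopulation in the clinical fit. A
  covariate-dependent mode (inverse-logit in `Z`, intercept solved so the
  marginal rate is exact) is available, since in reality reserve
  exhaustion is not random; the random default keeps the covariate-target
  relationship homogeneous across subpopulations, which is also what the
  simulation scenarios assume.
* **Outcomes.** In every scenario the target follows the informative
  linear model for *all* subjects, then is affinely rescaled per
  realization to sample mean 0 and SD exactly 50. Scenario `sim1` draws
  the uninformative subpopulation's surrogate from an alternative linear
  model whose slopes are redrawn each replication from `N(0, 0.176)`;
  `sim2` draws it as covariate-free noise `N(0, sigma_I)`.
* **Missingness.** The target can be masked completely at random or with
  logit-linear covariate dependence (`apply_missingness()`), emulating the
  incomplete 90-day follow-up that motivates the propensity-weighted
  evaluation.

### Residual scales: the one genuinely free choice

The clinical fit's residual SDs were never published, so `sigma_V` and
`sigma_I` had to be chosen. The published fit *does* report one separation
diagnostic — a relative classification entropy of about 0.6 — and the
package calibrates to it: the default `signal_r2 = 0.9` sets
`sigma_V = sqrt(Var(Z beta_V) * (1 - 0.9) / 0.9)` (about 0.22 on the
surrogate scale), which makes a two-component fit to a cohort-scale draw
(`n = 4737`, scenario `sim2`) attain relative entropy of roughly
0.59-0.61. `sigma_I = 2 * sigma_V` keeps the uninformative subpopulation
noisier than the informative one. An earlier candidate default
(`signal_r2 = 0.5`) was rejected because it produces a regime in which
even the exactly-maximized mixture likelihood cannot separate the
subpopulations (we verified this by initializing EM at the true labels:
it converges to the same diffuse optimum), which contradicts the
well-separated behaviour the published analysis reports; it remains
reachable through `generative_params(signal_r2 = ...)` for studying the
weak-separation regime.

The theory scenario is the stylized two-subpopulation model in which the
target literally equals the surrogate plus error for V-subjects
(`T = S + e`) while `S` is noise for I-subjects. To keep the mixture
identity

$$ E[T \mid S] \;=\; P(V)\,S + \bigl(1 - P(V)\bigr)\,E[T] $$

exact — which is what demonstrates the failure of full-surrogacy
conditions, since `E[T | S, Z]` retains a `Z` term — the generator gives
`S` the *same* marginal in both subpopulations (`N(0, sigma_I)` for
everyone) and applies the target's affine normalization map to `S` as
well. Drawing `S | V` from the covariate model instead would make
`P(V | S)` vary with `S` and the identity would fail by construction; the
identity, not the covariate model for `S`, is the point of this scenario.

## Evaluation machinery

* **AUC.** Weighted Mann-Whitney statistic with ties counted 1/2, exact
  under ties, computed in `O(n log n)` by accumulating negative-class
  weight below each score group. Unweighted intervals use the asymptotic
  placement-value (DeLong) variance; weighted intervals use a
  class-stratified bootstrap (default 2000 resamples), since placement
  asymptotics do not carry over cleanly to arbitrary weights.
* **Paired AUC comparison.** Placement-value (structural-components)
  variance of the AUC difference of two scores on the same subjects; the
  published analysis does not name its test, and this is the standard
  correlated-AUC construction. A paired stratified bootstrap backstops
  the degenerate case of zero placement variance.
* **Spearman comparison.** The permutation scheme swaps the pair
  `(R1_i, R2_i)` independently with probability 1/2 per subject: under
  the null that the two scores are exchangeable given the target, this
  preserves each score's marginal and its coupling to `T`. P-values carry
  the add-one correction, so the smallest attainable value is
  `1/(n_perm + 1)`.
* **Missing targets.** Evaluation restricts to observed-target subjects
  and reports `n_effective`. `propensity_weights()` fits the logistic
  model of observation on `Z` and returns inverse-probability weights
  (clipped at the 99th percentile, normalized to mean 1); the literal
  "propensity as weight" variant is exposed as `type = "propensity"` for
  sensitivity analysis. `auc_sweep()` recomputes the weighted AUC
  difference over a cutoff grid (default 5 to 25), reporting pointwise
  bootstrap intervals and flagging — not dropping — cutoffs where a class
  is empty.
* **Outcome direction.** Larger synthetic `T` means worse outcome, and
  the positive class is `T > cutoff`; `direction = "less"` flips this for
  data oriented the other way.

## Numerical choices

* EM initialization: per-row symmetric Dirichlet(1) responsibilities;
  default 20 restarts (5 inside the simulation studies, where the
  components are well separated and restarts are cheap insurance rather
  than necessity), relative log-likelihood tolerance 1e-8, at most 500
  iterations (1500 in long-running study configurations).
* Degeneracy: a component whose responsibility mass falls below `p + 2`
  effective observations, or whose residual variance falls below
  `1e-6 * var(y)`, aborts that start; the initialization is redrawn, up
  to three times the requested number of starts, and the fit errors only
  if every attempt degenerates. The variance floor is what makes
  unconstrained component variances safe against likelihood blow-up on
  interpolating components.
* `BIC = -2 log L + q log n` with `q = K(p + 2) - 1` free parameters for
  the mixture (slopes, intercept and variance per component, plus `K - 1`
  mixing weights) and `q = p + 2` for the pooled model; residual variances
  are maximum-likelihood (divide by `n`), matching the likelihood the BIC
  penalizes.
* Ties: modal assignment breaks posterior ties toward the informative
  component when known, else the lowest index; informative-component
  near-ties emit a warning rather than an error.
* Quantiles in study summaries are `quantile(type = 7)` (linear
  interpolation of order statistics); the relative MSE reduction is
  reported both as `1 - mean(mse_mix)/mean(mse_lin)` and as the mean
  per-replication reduction, because the two constructions differ and
  either could be meant by a single summary number.
* All generators and fits are pure functions of their seed; study-level
  seeds derive per-replication seeds deterministically.

## Problem sizes used by the shipped checks

The test suite exercises the full pipeline at sizes chosen to make the
statistical assertions sharp while remaining desk-scale: EM correctness on
50 random datasets of up to 500 subjects; planted-structure recovery at
`n = 2000`; metric oracles on 100 random tied instances up to `n = 200`;
test size under the null with 1000 (AUC) and 500 (permutation)
replications; both simulation scenarios at `n = 2000` with 200
replications; and the conditional-mean identity at `n = 100000` with 50
equal-count bins. The acceptance script reruns the two studies at 100
replications of `n = 2000` and the remaining computations at the same
sizes.

## What passing these checks does and does not show

The generator reproduces the *structure* the method assumes — latent
two-subpopulation membership, a shared covariate-target model, a
surrogate that is informative in one subpopulation only — under exactly
Gaussian errors, exactly linear signals, and a correctly specified number
of components. Real cohorts offer none of those guarantees: creatinine
change is right-skewed, covariate effects are not exactly linear, there
may be more than two reserve phenotypes, and membership is certainly not
independent of covariates. Passing the shipped checks therefore
demonstrates that the estimator and metrics do what they claim under the
model, not that a two-component mixture is an adequate description of any
particular clinical population. The published clinical coefficient tables,
AUCs and entropy depend on an undeposited dataset and are deliberately not
asserted anywhere; they enter only as generator defaults (slope vectors,
mixing proportion, the entropy calibration target).

Known limitations: the informative-component heuristic (largest mean
absolute slope) presumes standardized covariates and can mis-select under
near-ties; BIC comparison across `K` is supported but no automatic
selection of `K` is attempted; the propensity model is a plain logistic
fit with no penalization, so separation raises an error rather than being
absorbed; and the sweep's bootstrap intervals are pointwise, not
simultaneous.
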