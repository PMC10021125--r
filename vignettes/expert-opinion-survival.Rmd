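---
title: "Incorporating expert opinion into parametric survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incorporating expert opinion into parametric survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elicitsurv)
```

## The model

For `n` subjects with observed times `t_i` (event or censoring,
whichever came first) and event indicators `v_i`, and a parametric
family with parameters `θ`, the right-censored likelihood is
`Π f(t_i)^{v_i} S(t_i)^{1 − v_i}`, equivalently `Π h(t_i)^{v_i} S(t_i)`.
Expert opinion enters on the *observable* scale, never the parameter
scale: an expert (or a pool of experts) holds a density `π_{t*}` over a
quantity the model can predict — `S(t*)` at a landmark time `t*`, or
the median or mean survival. The log of that density, evaluated at the
model-implied value, is added to the log-likelihood:

* read as a Bayesian loss-function update, the posterior is
  `π(θ | D, φ) ∝ L(θ | D) · Π_k π_{t*_k}(q_k(θ)) · π(θ)`;
* read as penalized maximum likelihood, the same sum is maximized
  without the prior.

For a single normal expert about `S(t*)` under an exponential model the
penalty is exactly
`exp{−½ ((e^{−θ t*} − μ_expert)/σ_expert)²}` — a useful hand-checkable
special case that the test suite pins down numerically.

Assumptions worth stating: subjects are i.i.d. within the chosen
family; censoring is noninformative; the expert density is a genuine
probability statement about the observable (so a diffuse opinion
contributes a near-constant and changes nothing, which the tests
verify); multiple opinions at different timepoints multiply, i.e. are
treated as independent pieces of evidence.

## Families and parameterizations

Eight families: exponential (rate), Weibull AFT (shape, scale), gamma
(shape, rate), Gompertz (hazard `b·exp(a t)`, `a` may be negative, in
which case survival plateaus at `exp(b/a)` and the median/mean may not
exist — such requests error informatively), log-normal, log-logistic,
generalized gamma in the (μ, σ, Q) form, and Royston–Parmar: a
restricted cubic spline for log cumulative hazard against log time.
Default spline knots: boundary knots at the extreme uncensored log
event times, one internal knot at their median (configurable). With no
internal knots the spline is exactly a Weibull PH model.

All fitting happens on an unconstrained transformed scale (log for
positive parameters, identity otherwise); results are reported on the
natural scale. A single binary covariate is supported — proportional
hazards for the hazard-parameterized families (exponential, Gompertz,
Royston–Parmar), accelerated failure time for the time-scale families.

Numerical choices: the generalized-gamma density switches to its exact
log-normal limit for `|Q| < 1e−5`, because the `Q^{−2}`-scale terms
lose all floating-point precision below that and can otherwise produce
spuriously inflated likelihoods an optimizer will happily exploit (we
found exactly that during development). Medians use closed forms where
they exist and bracketed root-finding otherwise; means use closed forms
or adaptive quadrature of `S` with a required finite horizon for
improper survival functions.

## Fitting elicited judgements

A raw judgement is (LPL, MLV, UPL) with a coverage level, by default
99%, read as a central interval: LPL and UPL are the 0.005 and 0.995
quantiles. Candidate families are normal, Student-t with 3 df,
log-normal, gamma, and (for probabilities only) beta. Each candidate
minimizes

```
(q_fit(α) − LPL)² + (q_fit(1−α) − UPL)² + (mode_fit − MLV)²
```

with equal weights, all on the value scale of the elicited quantity;
the best-scoring family wins. We deliberately measure the two limit
errors in *quantile* (value) space rather than probability space.
With limits as extreme as 0.005/0.995, the probability-space objective
is degenerate: any location-scale candidate can satisfy the mode and
one limit exactly and lose only `α² = 2.5e−5` on the other by shrinking
its scale toward zero, so all families tie at a collapsed, absurdly
confident fit. In value space the terms are commensurable and the
qualitative behavior practitioners expect emerges — e.g. an expert
whose MLV sits near the LPL of a wide interval gets a right-skewed,
high-variance best fit.

## Pooling

Linear pooling is the weighted mixture `Σ w_j π_j`; logarithmic pooling
is the weighted geometric mean `Π π_j^{w_j}` renormalized by adaptive
quadrature over the union of the components' `1e−9` tail brackets (the
truncated mass is below the `1e−8` accuracy the pooled density is held
to; the normalizer is cached on the pool object). Defaults: equal
weights. For probability-scale quantities the support is clipped to
`[0, 1]`. Logarithmic pooling is externally Bayesian (pool-then-update
= update-then-pool; exact in the gamma/exponential conjugate case,
which the tests verify in closed form) but violates marginalization;
linear pooling is the reverse, and is order-dependent: pooling priors
then updating differs from pooling posteriors. The test suite
demonstrates both coherence failures numerically on the two-gamma
example.

The penalty uses the pooled density *exactly* — a multimodal linear
pool is evaluated as the mixture it is, never approximated by a single
distribution. The logarithmic pool's normalizing constant is included;
it is constant in `θ`, so inference is unaffected, but deviances remain
comparable across pooling choices.

## Inference

`fit_penalized_ml()` maximizes log-likelihood plus penalty by
multi-start Nelder–Mead exploration with BFGS polish on the transformed
scale; the curvature at the optimum supplies a Gaussian approximation.
`fit_mcmc()` is an adaptive random-walk Metropolis sampler: Gaussian
proposals whose covariance adapts during burn-in to
`2.38²/d` times the empirical covariance of the history. Defaults
mirror common practice for these models: 3 chains of 10,000 iterations,
first half discarded. Chains initialize at the penalized-ML optimum,
jittered, falling back to dispersed moment-based starts. Split-R̂ is
computed and a warning raised above 1.05. Every stochastic entry point
takes an explicit seed.

Default priors are weakly informative: Normal(0, 5) on each transformed
parameter, except the generalized-gamma shape `Q`, which gets
Normal(0, 2.5). The exception is deliberate: `|Q| > 5` has no practical
meaning, and under a flatter prior the sampler wanders onto the
unidentified large-`|Q|` ridge where the posterior-mean plug-in lands
off the ridge and DIC's `p_D` goes negative. `preset_priors()` provides
the two specifications used in the prior-sensitivity study: flat
Uniform(−20, 20) on every transformed parameter, and a deliberately
more informative "vague" set (Gamma(1, 0.1) on positive parameters,
Normal(0, 2.5) on real ones). Priors of gamma type apply on the natural
scale of positive parameters with the log-Jacobian included.

Degenerate inputs: zero-event datasets are accepted with a warning
(the likelihood is driven by censoring alone); single-subject datasets
are allowed; a `−Inf` penalty (model-implied quantity outside the
pooled support, or an undefined median) is returned as a rejection, not
an error.

## Model comparison

The deviance is `D(θ) = −2 (log L + log penalty)`, so DIC measures fit
to data *and* opinion jointly; `include_penalty = FALSE` gives the
data-only deviance as a sensitivity. `p_D = D̄ − D(θ̄)` with `θ̄` the
posterior mean on the transformed scale, back-transformed (natural-
scale means of constrained parameters can be invalid). A negative
`p_D` is a red flag for ridge-shaped posteriors — see the prior note
above. Ranking is by ascending DIC with alphabetical tie-breaks.

## What the synthetic-data generator emulates

`simulate_survival_data()` draws event times by inverse-CDF sampling
from any supported family and applies administrative, exponential, or
fraction-targeted censoring. It emulates the essential structure of a
maturing trial read-out — i.i.d. event times, noninformative censoring
concentrated at a data cut-off — and nothing else: no accrual ramp, no
dropout informatively linked to prognosis, no covariate mix, no
inter-site heterogeneity. A green simulation test therefore establishes
that the estimators recover the truth of *this* idealized world, not
that real trial extrapolations are reliable.

Synthetic experts (`simulate_expert_opinion()`) are normal densities
centered at `(1 + bias) · S_true(t*)`. The default width makes the 99%
opinion interval span ±0.15 on the probability scale (sd ≈ 0.058).
Representative generating truths for the studies (time unit ≈ years,
chosen to resemble a maturing oncology read-out with 30–70% censoring
at cut-off): exponential rate 0.25; Weibull (1.3, 4); gamma (1.5,
0.4); Gompertz (0.08, 0.2); log-normal (1.2, 0.8); log-logistic (1.6,
3.5); generalized gamma (1.2, 0.8, 0.6); the Royston–Parmar study fits
the spline to Weibull-generated data. Default bias grid
{−0.40, −0.25, −0.10, 0, +0.10, +0.25}; default extrapolation horizon
3× the censoring time.

## Design choices made where the design was open

* **Elicitation objective in value space** — see above; the
  probability-space variant is degenerate at 99% coverage.
* **Coverage read as a central interval** (0.005/0.995 quantiles for
  99%), the standard SHELF-style reading.
* **DIC deviance includes the opinion term by default**, since the
  point of the method is joint fit; the flag exposes the data-only
  variant.
* **Time units are whatever the data use**; opinion timepoints must be
  on the same scale and are validated only for ordering.
* **JSON opinion configs** (a YAML parser is not among the package's
  dependencies; the format is a direct transliteration).

## Known limitations

* The bias study shows the two-sided truth about miscalibrated
  experts: with the default (tight, ±0.15-at-99%) synthetic opinion, an
  unbiased or mildly biased (|bias| ≤ 10%) expert clearly improves
  extrapolation RMSE, and even a 40%-pessimistic expert rescues a
  misspecified model, but at ±25% relative bias a *tight* wrong expert
  is slightly worse than data alone for a correctly specified model —
  a 25% bias is a 2σ miscalibration at that width. Wider (more honest)
  opinion intervals shift this break-even outward.
* DIC near-ties among nested families are intrinsically noisy: a
  nested competitor with `k` extra parameters beats the true smaller
  model by more than 2 DIC with probability ≈ `P(χ²_k > 2k + 2)` ≈ 5%
  per family, so with several flexible competitors the true family
  falls more than 2 units behind the best in roughly 15–30% of
  replicates even on exactly constant-hazard data. Rankings should be
  read with that noise floor in mind (the paper-style observation that
  all DICs within ~3 units are "broadly similar" is the right
  granularity).
* For 3-parameter families at n ≈ 100 the posterior of extrapolated
  survival has a Monte-Carlo noise floor of ~0.01 (max over a grid) at
  15,000 retained draws; prior-sensitivity statements below 0.02
  should be averaged over seeds for production use.
* One binary covariate; no interval censoring or left truncation; no
  opinions on between-arm survival differences (extension point: an
  `opinion_constraint` whose implied quantity is `S₁(t*) − S₀(t*)`).
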