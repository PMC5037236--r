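---
title: "Estimation methods and simulation design in irtlab"
author: "irtlab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimation methods and simulation design in irtlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The models

irtlab estimates the one- and two-parameter logistic item response models.
A person $i$ with latent ability $\theta_i$ answers item $k$ (difficulty
$b_k$, discrimination $a_k > 0$) correctly with probability

$$P(Y_{ik}=1 \mid \theta_i, b_k, a_k)
  = \frac{\exp\{a_k(\theta_i - b_k)\}}{1 + \exp\{a_k(\theta_i - b_k)\}},$$

with all $a_k \equiv 1$ under the 1PL (Rasch) model. Responses are locally
independent given the parameters, so the likelihood is a product of
Bernoulli terms. All logistic evaluations go through numerically stable
branches and are safe for logits up to $\pm 700$.

Four estimation families share this core:

* **CML** (1PL only) — conditional maximum likelihood. The raw score is
  sufficient for ability, so conditioning on it eliminates the person
  parameters. The conditional likelihood is built from elementary symmetric
  functions $\gamma_r$ of the easiness values $\varepsilon_k = e^{-b_k}$ and
  maximized by Newton–Raphson with the analytic gradient and Hessian
  (first- and second-order partial ESF tables). Difficulties are normalized
  to sum to zero; persons with extreme raw scores carry no conditional
  information and are excluded from item estimation, then scored like
  everyone else.
* **MML** — Bock–Aitkin EM against a fixed N(0,1) ability distribution,
  approximated on 41 equally spaced nodes on $[-5, 5]$ with renormalized
  normal weights. The M-step is a per-item weighted logistic Newton update
  (slope fixed at 1 for the 1PL) guarded so the marginal likelihood never
  decreases. The ability distribution is not updated. Item SEs use the
  per-person score contributions of the marginal likelihood (empirical
  information, cross-item blocks ignored).
* **MCMC** — Metropolis-within-Gibbs, written in C++. Abilities,
  difficulties, and (2PL) log-discriminations take univariate Gaussian
  random-walk steps against their full conditionals; hierarchical
  population means and precisions are conjugate Gibbs draws. Proposal SDs
  adapt only during burn-in (windows of 50 iterations, acceptance target
  0.3–0.5), so the retained chain has the correct stationary distribution.
  Defaults follow the study protocol: a single chain, burn-in 5000,
  1000 retained draws, initial values 0 (hierarchical SDs 1); the
  posterior mean is the point estimate and the posterior SD the reported
  SE. Discriminations are sampled on the log scale, where the lognormal
  prior is normal.
* **VB** — coordinate-ascent mean-field variational Bayes with one
  Gaussian factor per ability, difficulty, and log-discrimination (plus
  Gaussian/Gamma factors for hierarchical hyperparameters). The logistic
  expectation is handled by the Saul–Jordan upper bound on
  $E[\log(1+e^Z)]$, $Z \sim N(m, v)$, with one variational parameter
  $\xi_{ik}$ per response, re-tightened every sweep by solving
  $\xi = \sigma(m + (1-2\xi)v/2)$. For the 2PL the logit
  $a_k(\theta_i - b_k)$ is not Gaussian under the factorized posterior;
  its exact first two moments (using lognormal moments of $a_k$) are
  matched to a Gaussian before the bound is applied — exact for the 1PL.

## Prior regimes

Every normal and lognormal prior is parameterized as (mean, variance):

* *matched*: $\theta, b \sim N(0,1)$; $\log a \sim N(0, 0.25^2)$ — the
  generating distributions themselves.
* *standard vague*: $\theta \sim N(0,1)$, $b \sim N(0, 10^3)$,
  $\log a \sim N(0, 8)$. The 8 is read as a variance, consistent with the
  "large variance" role it plays next to $10^3$; this reading is recorded
  as an open choice.
* *hierarchical*: $\theta \sim N(m_\theta, u_\theta^{-1})$,
  $b \sim N(m_b, u_b^{-1})$, $\log a \sim N(m_a, u_a^{-1})$ with
  $m \sim N(0, 10^6)$ and $u \sim \mathrm{Gamma}(1, 1)$ (shape–rate, on
  precisions).

The hierarchical regime is deliberately shift-unidentified (and, for the
2PL, scale-unidentified): the likelihood constrains only
$a_k(\theta_i - b_k)$, and the $N(0,10^6)$ hyper-means let the common
location float. Point estimates remain fine after alignment (below), but
the MCMC posterior SD of the difficulties inflates with the slow random
walk of the common shift — the mechanism behind the large hierarchical
difficulty SEs in the study tables. How much it inflates in a 5000 + 1000
iteration run is a property of the sampler's mixing speed, not of the
posterior, and differs between samplers.

## VB numerical design

Each sweep updates, in order: all $\xi_{ik}$; the ability block; the
difficulty block; the (2PL) log-discrimination block; then hierarchical
hyper-factors in closed conjugate form. A block update takes one Newton
step on the factor means together with the stationary-point update of the
factor variances, both from single-pass sufficient statistics computed in
C++, and accepts coordinates only where the block's local objective does
not decrease (step-halving otherwise). Because every move is an ascent
step on one global objective, the bound trace is non-decreasing — an
invariant the test suite asserts — and `vb_bound_value()` recomputes the
objective from scratch as an audit.

Coordinate ascent crawls along the model's weakly identified shift/scale
directions, so each sweep ends with an exact *mode jump*: the
likelihood-equivalent reparameterization
$(\theta, b, a) \to (c\theta + d,\; cb + d,\; a/c)$ leaves the bound's
likelihood part unchanged, and the prior/entropy part is optimized over
$(c, d)$ directly (shift only for the 1PL). Initialization: factor means
0, variances 1, $\xi = 1/2$, Gamma factors at (1, 1). The stopping rule
compares the per-sweep bound improvement to `tol` (default $10^{-6}$,
cap 500 sweeps); hitting the cap sets a warning flag rather than failing,
since near-converged factors are still usable estimates. The study harness
uses `tol` $= 10^{-5} S L$ — the objective is a sum over $S \times L$
response terms, and at that threshold point estimates are stable to well
under 0.01 — with a 300-sweep cap.

VB with the standard-vague prior on the 2PL reproduces the known
pathology of that configuration: the discrimination factors can collapse
toward zero and the fit fails to converge. It is implemented and flagged,
but excluded from headline comparisons, mirroring how that configuration
is dropped from the study tables.

## Identifiability alignment and metrics

Estimates are compared to the truth only after removing the 2PL
shift/scale ambiguity: $\theta' = s\hat\theta + t$, $b' = s\hat b + t$,
$a' = \hat a / s$, with $(s, t)$ minimizing
$J(s,t) = \mathrm{RMSE}(\theta) + \mathrm{RMSE}(b) + \mathrm{RMSE}(a)$
(21×21 grid pre-scan on $s \in [0.5, 2]$, $t \in [-1, 1]$, refined by
Nelder–Mead on $(\log s, t)$). For the 1PL the unit slopes fix the scale:
$s = 1$ and only the shift is optimized, which is what lets sum-to-zero
CML difficulties reach their small RMSEs when the true difficulties have a
nonzero sample mean. The discrimination transform is taken as $a/s$ — the
form under which $(\theta', b', a')$ is likelihood-equivalent to
$(\theta, b, a)$; the alternative printed form $a \cdot s$ is not an
equivalence transform and cannot recover planted transforms of the truth.

Recovery metrics are root-mean-square errors over persons (ability),
items (difficulty, discrimination), or person-item response probabilities,
computed within each replication and then averaged with equal weight over
replications ("RMSE then average" — the standard reading in the
simulation literature). Probability RMSEs use the estimates as reported
(they are invariant to the alignment transform). Reported "SEs" are
information-based (CML/MML), posterior SDs (MCMC), or factor SDs (VB),
averaged over parameters within a replication and then over replications.
Effect sizes come from a fixed-effects ANOVA of the per-replication
metrics on estimation method, sample size, and test length (all
interactions), with $\eta^2 = SS_{\text{effect}}/SS_{\text{total}}$ and
the 8% / 14% medium/large conventions.

## The synthetic-data generator

Abilities and difficulties are drawn iid N(0, 1); 2PL discriminations iid
lognormal with log-mean 0 and log-SD 0.25; responses are thresholded
uniforms against the model probabilities. One root seed per replication is
hashed (never with the estimation method) into separate substreams for
parameter draws, response thresholds, and fitter randomness, so every
method within a replication sees the identical data set — the paired
design the study's comparisons assume. True parameters are not re-centered
after drawing; the alignment step absorbs location and scale.

What the generator does *not* emulate: non-normal ability distributions,
missing responses, guessing (3PL lower asymptotes), polytomous items, or
local dependence. Recovery results under these conditions say nothing
about robustness to their violation.

## Problem sizes and reproducibility

The full crossed design is 4 sample sizes (250–2000) × 3 test lengths
(10–40) × up to 8 methods. The package's own consistency checks and the
bundled acceptance script run reduced-replication versions of this design
(100 replications for CML, which fits in milliseconds; 20 for VB; 10 and
fewer for MCMC, whose 6000-iteration protocol dominates the cost); at
these sizes the Monte-Carlo error of every reported aggregate is well
below the 0.01-level resolution of the comparison tables. Exact
reproducibility is end-to-end: a study configuration plus a root seed
fixes every number in every output file, and per-cell CSVs let an
interrupted study resume without recomputation.

## Known limitations

* CML is undefined for the 2PL (sufficiency fails); requesting it errors.
* The MCMC kernel is adaptive random-walk Metropolis within Gibbs. Its
  posterior *means* match exact quadrature on small instances (tested),
  but quantities driven by mixing speed under weakly identified priors —
  notably the hierarchical difficulty posterior SD within a 1000-draw
  window, and any failure-to-converge behavior under variance-$10^3$
  priors — are sampler-specific and will not match other samplers' values.
* The 2PL VB objective uses moment matching inside the Saul–Jordan bound;
  it is a principled approximation but, unlike the 1PL case, no longer a
  strict lower bound on the marginal likelihood.
* Reported SEs are within-replication uncertainty summaries; they are not
  sampling SDs across replications.
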