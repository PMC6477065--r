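---
title: "Modelling associative learning under volatility: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling associative learning under volatility: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the task, the three learning models and their inversion, random-effects
model selection, the cohort statistics, and — because every stage must be
testable without participant data — the synthetic-cohort generator and
what it does and does not emulate.

## The task

The probabilistic associative learning (ProAL) task presents a tone cue
(low/high) followed by a face outcome (male/female). The binary input the
models track is the *match indicator* `u`: 1 when the trial realises the
reference association (high tone followed by a female face, equivalently
low tone by a male face). Both cue types share one contingency parameter,
so a single tracked probability suffices — this is why `u` encodes
congruence rather than the raw outcome category, matching the
one-dimensional second level of the hierarchical model.

`canonical_schedule()` fixes the default session: 150 trials, 10 blocks,
lengths `15, 16, 11, 17, 14, 16, 15, 13, 17, 16`, contingencies
`0.5, 0.9, 0.1, 0.7, 0.3, 0.9, 0.5, 0.1, 0.7, 0.5`. The published design
specifies the session length, the number of blocks, the length range
11–17 and the three contingency levels, but not the exact per-block
sequence; the sequence above is a package choice that attains both extreme
block lengths and uses all three levels together with their complements.
Cues are fair-coin i.i.d. (cue base rates are not otherwise constrained)
and trial indices are 1-based throughout.

## Perceptual models

**Three-level binary HGF.** The generative model places a Gaussian random
walk on the logit contingency `x2` whose step variance
`exp(kappa * x3 + omega2)` is modulated by a second random walk `x3`
(volatility) with step variance `exp(omega3)`. Filtering is the standard
single-sweep prediction/update recursion for the binary HGF: predictions
equal the previous posteriors, the level-1 prediction is
`muhat1 = sigmoid(mu2)`, precision predictions are
`pihat2 = 1 / (sigma2 + exp(kappa * mu3 + omega2))` and
`pihat3 = 1 / (sigma3 + exp(omega3))`, level 2 updates by the outcome
prediction error `delta1 = u - muhat1`, and level 3 by the volatility
prediction error `delta2`. The recursion is implemented in C++
(`src/filters.cpp`) because model inversion evaluates it hundreds of
thousands of times; a scalar R oracle in the test suite pins each update
equation to 10 decimal places.

Two structural facts are worth knowing. First, with `kappa = 0` the third
level decouples and `mu3` stays at its initial value — the filter then
behaves as a fixed-volatility learner (asserted in the tests). Second, not
every parameter combination is admissible: for `omega2` above roughly
−1.5 on this task the level-3 precision can turn negative, in which case
the filter raises a classed error (`proalhgf_invalid_regime`) and the
fitting objective treats the region as a large finite penalty.

**Rescorla–Wagner.** A fixed-rate delta rule,
`v(k) = v(k-1) + alpha * (u(k) - v(k-1))`, the classical benchmark for
probability learning without volatility tracking.

**Sutton K1.** A single-predictor gain-adaptation rule: the log learning
rate `beta` moves with the correlation between the current prediction
error and an eligibility trace `h`, and the effective rate is capped at 1:

```
beta(k)  = beta(k-1) + mu_meta * delta * h(k-1)
alpha(k) = min(exp(beta(k)), 1)
v(k)     = v(k-1) + alpha(k) * delta
h(k)     = (h(k-1) + alpha(k) * delta) * max(0, 1 - alpha(k)),  h(0) = 0
```

The published analysis names SK1 as a competitor but leaves its exact
variant and free-parameter set to an unavailable supplement; the package
fixes `beta0 = log(0.1)` and frees `mu_meta` (log-space prior) and `zeta`,
giving a stable two-free-parameter competitor. With `mu_meta = 0` the
model reduces exactly to RW with `alpha = exp(beta0)` (tested).

**Response model.** All three models share the unit-square sigmoid
`p(y = 1) = muhat1^zeta / (muhat1^zeta + (1 - muhat1)^zeta)` with inverse
decision noise `zeta`; using the same response family across models keeps
the model evidences comparable. In the likelihood, `muhat1` is clipped to
`[1e-4, 1 - 1e-4]` so the log-likelihood stays finite, and log response
probabilities are evaluated on the logit scale so a confident wrong
prediction contributes a large finite penalty rather than `-Inf`. Missing
responses contribute nothing to the likelihood, but the inputs of those
trials still update beliefs.

## MAP inversion and Laplace evidence

Free parameters are estimated in unconstrained spaces — identity for
`omega2`/`omega3`, log for `zeta` and `mu_meta`, logit for the RW
`alpha` — under Gaussian priors. The defaults,

| model | parameter | prior (estimation space) |
|---|---|---|
| HGF | `omega2` | N(−3, 4²) |
| HGF | `omega3` | N(−6, 4²) |
| all | `log zeta` | N(log 48, 1) |
| RW  | `logit alpha` | N(logit 0.3, 1) |
| SK1 | `log mu_meta` | N(log 0.05, 1) |

follow common binary-HGF conventions (the study's exact priors live in an
unavailable supplement) and are fully configurable. `kappa` is fixed at 1
(the study fixes it without printing the value), and the initial states
default to `mu2_0 = 0, sigma2_0 = 0.1, mu3_0 = 1, sigma3_0 = 1`.

`fit_map()` minimises the negative log joint by BFGS from 8 (default)
prior-dispersed starts, the first start being the prior mean; convergence
tolerance is 1e-6 on the objective, and everything is reproducible via a
counter-based seed scheme. The log model evidence is the Laplace
approximation `lme = -nlj + (d/2) log(2*pi) - log det(H) / 2` with `H` the
central-difference Hessian (step 1e-4 in estimation space). The same
estimation-space convention is used for fitting and for the evidence, so
evidences are comparable across models.

Two numerical conventions deserve a note. Inadmissible parameter regimes
map to a large finite objective value (1e10) rather than `Inf`, so the
quasi-Newton line search can back off. And when a subject's constrained
mode sits against the admissibility boundary, the finite-difference
Hessian can be indefinite there; `fit_map()` then prefers the best
*interior* restart optimum with a positive-definite Hessian, and if none
exists it projects the Hessian to the nearest positive-definite matrix — a
conservative convention that penalises the model for that subject — and
flags the fit (`hessian_pd = FALSE`). This keeps cohort evidence matrices
finite without silently rewarding boundary artefacts.

Parameter recovery (`recover_parameters()`) simulates `n_sims` response
sets per subject from the fitted (or true) parameters, refits each, and
correlates original with mean-recovered values. At the study design — 36
agents on the 150-trial canonical schedule — `omega2` and `zeta` recover
with correlations around 0.95; `omega3` is weakly identified at this
design (recovery correlation near 0.1), consistent with the very small
between-subject spread the study reports for it. The package flags this
rather than assuming it away.

## Random-effects model selection

`rfx_bms()` implements the variational Dirichlet–multinomial recursion:
subject attributions `g[n, k] ∝ exp(L[n, k] + psi(alpha_k) -
psi(sum(alpha)))`, concentrations `alpha = alpha0 + colSums(g)`, iterated
to `max |d alpha| < 1e-6` (default `alpha0 = 1` per model). Exceedance
probabilities come from 1e5 seeded Dirichlet Monte Carlo draws; the
Bayesian omnibus risk compares the random-effects free energy `F1`
(including the closed-form Dirichlet KL) with the equal-frequency null
`F0 = sum_n [logsumexp_k L(n, k) - log K]` via
`bor = 1 / (1 + exp(F1 - F0))`, and protected exceedance probabilities are
`pxp = ep * (1 - bor) + bor / K`. Evidence-shift invariance (adding a
constant to a subject's row changes nothing) and the symmetric,
single-subject, and dominance limits are all pinned by tests against an
independent scalar implementation of the same recursion.

## Cohort statistics

* **Summaries** report sample SD, adjusted Fisher–Pearson skewness and
  bias-adjusted *excess* kurtosis; constant variables yield `NA` markers
  rather than errors.
* **Tukey ladder** searches `{-2, -1, -1/2, 0 (log), 1/3, 1/2, 1, 2}`,
  applies a `+1` offset when `min(x) <= 0`, and picks the rung minimising
  absolute sample skewness, breaking ties towards the identity. The
  selection criterion is a package choice: the study used the ladder for
  the right-skewed preschool verbal-abuse score but does not state its
  selection rule or the chosen exponent.
* **Regressions** are the four named OLS models predicting emotion-coping
  appraisal from the transformed preschool VAQ score and `omega2`
  (simple, full-with-interaction, and the two partial models), each with
  t-based 95% CIs, adjusted R², residual SE, the overall F test and the
  LOOCV prediction score `Q2 = 1 - PRESS / TSS`. Anxiety scores enter the
  mixed graphical model but are deliberately excluded as regression
  predictors, mirroring the published analysis.
* **Mixed graphical model**: nodewise L1-penalised regression (linear for
  continuous nodes, logistic for binary nodes, predictors standardised
  internally) over a 50-point log-spaced lambda path down to 1e-3 of the
  per-node lambda_max, per-node lambda selected by EBIC with
  `gamma = 0.25`, edges kept under the AND rule with the signed mean of
  the two standardised coefficients as weight (0 on sign conflict). These
  defaults mirror the documented conventions of the estimator family the
  study used.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws per-subject questionnaire scores and HGF
parameters from a latent Gaussian copula with these marginal choices:

* **Raw VAQ period scores** are zero-inflated lognormal before integer
  clipping to [0, 120] (zero weights 0.25/0.15/0.10 for
  preschool/childhood/adolescence; the positive branch is floored at 1 so
  the zero mass is exactly the configured weight). This reproduces the
  strong right skew and floor effects of self-reported abuse scores
  without claiming their exact law; the zero weights are package choices —
  the study reports only moments, medians and ranges.
* **RAS subscales and STAI totals** are rounded, range-clipped Gaussians
  with the published cohort moments; `zeta` is lognormal with the
  published mean and SD.
* **`omega2`** is normal *truncated to the filter's admissible regime*
  ([−14, −1.5] on this task), with the underlying parameters solved so the
  observed mean and SD match the published values (−5.46, 2.82). Simple
  truncation would have shrunk the realised SD and with it every
  downstream effect size.
* **Emotion coping** is generated structurally from the published
  two-predictor linear model — intercept 15.072, −0.891 per unit of
  log-transformed preschool VAQ, −0.282 per unit `omega2`, residual SD
  2.281 — then rounded and clipped to its 4–20 scale; RAS-total is the sum
  of its three subscales by construction.
* **Correlation targets** (`omega2` with childhood/adolescent VAQ:
  −0.379/−0.448) are calibrated on the *observed* score scale: a
  fixed-seed Monte Carlo fixed-point iteration finds the latent normal
  correlation whose transformed margins realise the target, since
  zero-inflation and rounding attenuate correlations nonlinearly.
  Unreported pairwise correlations default to zero and the target matrix
  is repaired to the nearest positive-definite correlation matrix if
  needed.
* **Item-level scores** (15 VAQ items at 0–8 per period, three 4-item RAS
  subscales at 1–5, 20 STAI items at 1–4) are uniform random compositions
  of each total; only totals feed the analysis.

Behaviour comes from `generate_behavior()`: one 150-trial session per
subject with the subject's own HGF parameters. Near the admissibility
boundary a rare input sequence can still break the filter; such a subject
receives a fresh session seed (up to five attempts) before an error is
raised.

What the generator does **not** emulate: reaction times and missing
responses (real sessions had up to 9 missing trials; simulated agents
always respond), within-session parameter drift, questionnaire measurement
error and recall bias, demographic structure beyond a male/female draw,
and any direct STAI→RAS structural path (anxiety correlates with coping in
the generated data only through shared predictors). Passing tests
therefore certify the *machinery* — filters, inversion, selection,
statistics — under a realistic effect structure, not the empirical claims
of any particular cohort.

## Problem sizes and reproducibility

The test suite exercises the pipeline at the study's scale where that is
cheap (36 subjects, 150 trials, 500 simulated cohorts for the regression
recovery study, 10 cohorts for the model-identifiability study, 20 seeds
for the graphical-model recovery study) and at reduced scale where only
the mechanics are at stake. All randomness flows from explicit integer
seeds through a counter-based derivation scheme, so every reported number
is bit-reproducible; `end_to_end_dataset()` writes a manifest (master
seed, full-precision config JSON, config hash) from which
`regenerate_from_manifest()` reproduces a bundle byte-for-byte.

## Known limitations

* `omega3` is close to unidentifiable at 150 binary trials; its recovery
  correlation is reported but not relied on anywhere.
* The Laplace evidence is a local approximation; for subjects whose mode
  hugs the admissible-regime boundary it is a flagged, conservative
  surrogate (see above).
* The mixed graphical model treats the cohort's binary gender variable as
  0/1 logistic; with 36 subjects the logistic nodewise regressions are
  honest but low-powered, matching the published analysis's own caveat
  about sample size.
* The canonical block sequence is a stand-in for an unpublished figure;
  all structural constraints it must satisfy are tested, the exact order
  is not claimed.
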