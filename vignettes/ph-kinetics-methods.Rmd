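---
title: "Methods: hierarchical Bayesian pH kinetics in fresh meat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian pH kinetics in fresh meat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phbayes)
```

## The model and its assumptions

`phbayes` describes the pH of a fresh meat product during chilled storage
as a two-phase curve: a linear acidification phase, driven by lactic acid
bacteria fermenting in the matrix, followed by a stabilisation phase once
the product's buffering capacity halts the decline. For an observation in
production batch $r$ at storage day $t$, under lactate dose $L$ (% w/w)
and packaging atmosphere $p$:

$$m(t) = \mathrm{pH0}_r - \beta \min(t, \theta), \qquad
  \ln \beta = \lambda L^{n} + \delta_p,$$

with $\mathrm{pH0}_r \sim N(\mu_{pH0}, \sigma_{pH0})$ a batch random
effect and observations $Y \sim N(m(t), \sigma_{pH})$. The assumptions
worth keeping in mind:

* **Shared breakpoint.** One stabilisation time $\theta$ serves every
  lactate/atmosphere condition. Condition-specific breakpoints would need
  a richer sampling schedule than four days per curve.
* **Shared initial pH within a batch.** All conditions of a batch start
  from the same latent $\mathrm{pH0}_r$, because formulation and packaging
  split a single meat batch.
* **Log-linear covariate effects.** Lactate acts on the log rate through
  $\lambda L^n$ and the atmosphere through an additive offset $\delta_p$.
  We read the exponent as applying to the dose ($L^n$), which is the only
  reading consistent with the plug-in arithmetic the estimates reproduce
  (e.g. $-\exp(-0.095 \cdot 2^1 - 2.430) \cdot 12.9 + 6.49 = 5.55$).
* **Homoscedastic Gaussian error**, one variance for all days and
  conditions; storage-temperature changes during the protocol are absorbed
  into the kinetic parameters rather than modelled.

Four variants differ in what is estimated: M1 fixes $n = 1$ and
$\theta = 15$ d, M2 frees $n$ only, M3 frees $\theta$ only, M4 frees both
(7/8/8/9 free population-level parameters). The fixed $\theta = 15$ is the
producers' use-by date; freeing it uses a $U(8, 22)$ prior, the use-by
date $\pm 7$ days.

## Parameters, units, defaults

| Parameter | Meaning | Units | Prior |
|---|---|---|---|
| `mu_pH0` | mean initial pH across batches | pH | $N(5.84, 0.11)$ |
| `sigma_pH0` | between-batch sd of initial pH | pH | half-$N(0, 0.1)$ |
| `sigma_pH` | measurement sd | pH | half-$N(0, 0.1)$ |
| `lambda` | lactate slope on log rate | per (% w/w)$^n$ | $U(-1, 1)$ |
| `delta_Air`, `delta_MAP1`, `delta_MAP2` | atmosphere offsets on log rate | — | $U(-10, 10)$ |
| `n` | lactate scale exponent | — | 1 (fixed) or $U(-3, 3)$ |
| `theta` | stabilisation time | days | 15 (fixed) or $U(8, 22)$ |

The second argument of every normal/half-normal is a **standard
deviation** throughout (priors and likelihood) — never a variance or a
precision. The informative prior on `mu_pH0` comes from published
measurements on fresh poultry sausage; all `ph_priors()` components can be
overridden.

`ph_params()` defaults to the point estimates of the selected variant on
the motivating poultry-sausage study
($\mu_{pH0} = 6.49$, $\sigma_{pH0} = 0.10$, $\sigma_{pH} = 0.15$,
$\lambda = -0.095$, $\delta_{Air} = -2.430$, $\delta_{MAP1} = -2.487$,
$\delta_{MAP2} = -2.339$, $n = 1$, $\theta = 12.9$), so the default state
is a realistic generating truth for simulation studies.

## The synthetic-data generator

`simulate_ph_data()` draws data with exactly the generative structure the
model assumes, under the study design it emulates by default: 10
production batches × (3 lactate doses: 0, 1, 2 % w/w) × (3 atmospheres) ×
(sampling days 2, 8, 15, 22), one value per cell — 360 observations. One
observation per (batch, condition, day) matches the averaged-replicate
structure of the motivating dataset, where triplicate technical
measurements were averaged; `replicates_per_point` allows sensitivity
studies. The generating latent batch values ride along as a `"truth"`
attribute and are written to a **separate JSON sidecar** by
`write_ph_data()`, so a pipeline reading the CSV can never peek at them.

What the generator does *not* emulate: technical-replicate correlation
beyond iid noise, outliers (the kind a pH meter mishap produces),
temperature-shift effects, or day-dependent variance. Passing
recovery tests therefore demonstrates the estimator is consistent with its
own assumptions — not that real sausage data satisfy them.

## Inference: sampler design

The posterior is sampled by an **adaptive Gaussian random-walk
Metropolis-within-Gibbs** scheme, one block per free population-level
parameter per sweep:

* Proposal scales adapt by Robbins–Monro towards an acceptance rate of
  0.44 (the scalar-update optimum) **during burn-in only**; after burn-in
  they are frozen, so the retained chain is a valid Markov chain. The fit
  records the scales at freeze time and at the end, which are asserted
  identical in the tests.
* $\sigma_{pH}$ and $\sigma_{pH0}$ are proposed on the log scale with the
  Jacobian correction, keeping them positive without rejection waste.
* Latent $\mathrm{pH0}_r$ are refreshed by **conjugate Gibbs draws** — the
  mean is linear in $\mathrm{pH0}_r$, so the full conditional is normal —
  which mixes much better than MH for 10 weakly identified latents.
* The non-differentiable $\min(t,\theta)$ breakpoint is no obstacle to MH;
  $\theta$ proposals outside $U(8,22)$ are rejected via the prior.
* The likelihood is evaluated through cached residuals: each block update
  recomputes only the means it touches (an atmosphere offset touches a
  third of the data; a batch latent one tenth), which keeps a sweep at
  roughly 0.4 ms for 360 observations.

Chain starts (`initial_values = "auto"`) are overdispersed draws from the
priors, with uniform supports shrunk 10% from each boundary so no chain
starts at zero prior density; starting states are re-drawn (up to 100
times) until the log posterior is finite, which matters when zero-lactate
data meet a negative exponent draw. Defaults mirror the original analysis:
3 chains, 5,000 burn-in, 60,000 iterations thinned by 6 → 10,000 retained
draws per chain, 30,000 pooled. Retention starts at
`burn_in + thinning`, so the burn-in endpoint itself is never kept.

**Degenerate inputs.** An empty dataset is legal: the sampler then targets
the prior, which the tests exploit to check the $U(8,22)$ prior is
recovered. $0^n$ is defined as $0$ for $n > 0$; a state combining zero
lactate with $n \le 0$ has undefined rate and gets log posterior
$-\infty$, so the sampler auto-rejects it — this keeps the free-$n$
variants well-defined on zero-lactate data. $\sigma_{pH} = 0$ yields
$-\infty$ unless every residual is exactly zero.

The optional `fixed` argument pins any subset of parameters (including the
latent batch vector) at constants. It exists so conjugate closed-form
scenarios can be realised *through the real sampler* in tests, and doubles
as a profiling tool.

## Convergence diagnostics

`gelman_rubin()` computes the classical potential scale reduction from
between/within-chain variances, with one deliberate wrinkle: the pooled
variance estimate $\frac{n-1}{n} W + \frac{B}{n}$ is **floored at $W$**,
so chains with zero between-chain variance report exactly 1 instead of
$\sqrt{(n-1)/n} < 1$. Under-dispersion is thus reported as "converged"
rather than as a spurious sub-unit value; values meaningfully above 1
are unaffected. `geweke()` compares the first 10% and last 50% window
means, standardised by spectral standard errors from a batch-means
estimator (batch size $\approx \sqrt{m}$) — robust, dependency-free, and
adequate for the thinned, weakly autocorrelated chains produced here.
Pass thresholds default to $\hat R < 1.1$ and $|z| < 2$ and are
configurable in `diagnose()`.

## Model comparison and summaries

`compute_dic()` uses the Spiegelhalter construction:
$\bar D$ (mean of the per-draw observation deviances),
$D(\hat\vartheta)$ (deviance at the posterior mean of **all** sampled
quantities, latent batch values included), $p_D = \bar D - D(\hat\vartheta)$
and $\mathrm{DIC} = \bar D + p_D$. Two consequences, stated prominently:

* the hierarchical $\mathrm{pH0}_r$ term belongs to the **prior**, not the
  likelihood — the deviance is the observation-model deviance only, which
  pins down what $p_D$ means in this hierarchy;
* other engines use different penalties, so **absolute** DIC values are
  not comparable across software; within-package *ordering* on the same
  dataset is the meaningful output, and that is what the selection
  experiment in the test suite checks (the free-breakpoint variant wins on
  data generated with a between-sampling-days breakpoint).

Ties in `select_model()` break towards fewer free parameters (parsimony),
then variant order. Point estimates are posterior medians; intervals are
2.5%/97.5% quantiles of the pooled chains, computed by linear
interpolation between order statistics (R's default type 7). The plug-in
point for $D(\hat\vartheta)$ is the posterior **mean**, per the classical
DIC definition; medians are used only for reported summaries.

## Posterior-predictive simulation

`simulate_kinetics()` propagates every pooled draw through the mean curve
on a time grid and summarises pointwise (no simultaneous band — the bands
are pointwise by construction, like the figures they emulate). The default
mode draws a **new batch** initial pH per draw, so bands show kinetic
uncertainty plus batch variability; `mode = "mean_batch"` conditions on
the population mean, and `noise = TRUE` adds measurement error for a
single-measurement predictive band. Whether published credible bands
include measurement noise is ambiguous; both toggles are exposed and the
default excludes it.

## Problem sizes used in the tests

The suite favours many short chains over few long ones: unit-level MCMC
tests run 1–2 chains of a few thousand iterations on reduced designs
(2–5 batches); the closed-form agreement tests (conjugate posterior,
prior recovery, DIC quadrature) use single chains of 30,000–60,000
iterations on tiny datasets where sweeps are cheap; the recovery check
runs the full 360-observation design with 3 chains × 20,000 iterations
(thinned by 4, 5,000 burn-in), and the model-selection experiment uses 10
datasets × 4 variants with single 4,000-iteration chains, DIC needing no
between-chain statistics. These sizes give Monte-Carlo error comfortably
below each assertion's tolerance.

## Known limitations

* Temperature is not a covariate; kinetics are specific to the storage
  protocol that produced the data.
* O₂/CO₂ percentages enter only as a categorical atmosphere, not as
  continuous covariates.
* A single shared $\theta$ across conditions, and a single measurement
  variance, are modelling conveniences forced by sparse designs.
* No effective-sample-size or rank-normalised diagnostics; no WAIC/LOO.
* External datasets must be mapped to the five-column layout
  (`batch_id, lactate_pct, atmosphere, day, pH`) before use — the reader
  deliberately does not guess at foreign layouts. A converter is a few
  lines of dplyr: rename the batch, dose, atmosphere, day and response
  columns, recode atmosphere tokens to `Air`/`MAP1`/`MAP2`, and write
  with `write_ph_data()`.
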