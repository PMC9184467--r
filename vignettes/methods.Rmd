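---
title: "A hierarchical hurdle model for repeated emergence trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical hurdle model for repeated emergence trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Emergence-from-a-tube tests are a standard assay for boldness-related
personality traits in insects. Each trial of the design this package
targets yields two observations about one cricket: whether it left the
tube within the 10-minute window at all, and — if it did — how many
seconds it took (recorded between 1 and 599 s). Trials are repeated 7–10
times per individual, so the data are doubly structured: a binary process
and a conditional continuous process, both with repeated measures per
animal. The scientific questions are (i) whether densovirus-infected
animals behave differently from virus-free ones on average, (ii) whether
individuals differ consistently from each other (personality), and (iii)
whether those differences change with accumulated trial experience.

The model is a binomial–gaussian hurdle. Writing $x_t = t - \bar t$ for
the experience covariate centred at the dataset-wide mean trial index
(so intercepts describe behaviour averaged over the experiment), for
individual $i$ in trial $t$:

$$
\mathrm{stay}_{it} \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}(a_i + b_i x_t)\right),
\qquad
y_{it} \mid \mathrm{emerged} \sim \mathcal N(c_i + d_i x_t,\ \sigma_{\mathrm{res}}^2).
$$

All records inform the binomial part; only emerged records inform the
gaussian part. The four per-individual effects are the animal's
behavioural reaction norm — its average stay tendency ($a_i$, on the
logit scale), its experience trend in staying ($b_i$), its typical
latency ($c_i$, seconds) and its experience trend in latency ($d_i$,
seconds per trial) — and are drawn from group-specific normal
hyper-distributions, one set for virus-free and one for infected
animals:

$$
a_i \sim \mathcal N(\mu_a^{g(i)}, \sigma_a^{g(i)}), \quad
b_i \sim \mathcal N(\mu_b^{g(i)}, \sigma_b^{g(i)}), \quad \text{etc.}
$$

The binomial linear predictor models the logit of *staying* (not
emerging). This sign convention makes the infected group's intercept
larger than the virus-free group's, matching the direction of the
published group contrast, and the reported emergence probability is
$1 - \mathrm{logit}^{-1}(\eta)$.

### Priors

"Minimally informative" priors are made concrete on each parameter's
natural scale: $\mathcal N(0, 10^2)$ on the logit-scale hyper-means,
$\mathcal N(0, 1000^2)$ on the seconds-scale hyper-means, half-normal
$(0, 5^2)$ on the logit-scale hyper-SDs, and half-normal $(0, 200^2)$ on
the seconds-scale hyper-SDs and the residual SD. These are broad
relative to the observable ranges (a logit of 10 is a probability of
0.99995; latencies cannot exceed 599 s). All scales are adjustable via
`prior_config()`; doubling them moves the reduced-scale posterior
summaries by far less than one posterior SD.

### Deliberate simplifications

* The four effects are **independent** normals: no intercept–slope
  correlation is modelled, because the study reports only means and SDs
  of each effect distribution and the generative truth is unknowable
  from the published summaries.
* One residual latency SD is **shared** across groups and individuals —
  the simplest identifiable choice given that no per-group residual term
  is reported.
* The latency likelihood is an **untruncated** gaussian even though
  observed latencies live in \[1, 599\]: this mirrors the published
  modelling choice, which judged a gaussian adequate via posterior
  predictive checks (a gamma variant is deliberately out of scope).
* Individuals that never emerge still carry gaussian effects; those are
  identified by the hierarchy alone and simply shrink to their group
  distribution. This is accepted, not an error. A whole *group* with
  zero emergences, however, makes the group's gaussian hyperparameters
  unidentifiable and `fit_hurdle()` refuses it unless they are fixed.

## The sampler

No general-purpose MCMC engine is assumed; the posterior is sampled by
an adaptive Metropolis-within-Gibbs scheme written for this model:

* $(c_i, d_i)$: exact bivariate conjugate Gibbs updates;
* hyper-means: exact conjugate Gibbs given the effects;
* $a_i$, $b_i$: per-individual random-walk Metropolis, all individuals
  updated in one vectorised sweep, step sizes adapted during warmup
  toward 44 % acceptance;
* hyper-SDs and residual SD: random-walk Metropolis on $\log\sigma$;
* **funnel moves**: hierarchical variance parameters mix notoriously
  badly when updated conditionally on centred effects. Each sweep
  therefore adds joint proposals that translate $(\mu, \{e_i\})$
  together and rescale $(\sigma, \{e_i - \mu\})$ together. Both leave
  the random-effects prior term invariant (for the scaling move the
  Jacobian cancels it exactly, leaving a residual $\log k$ term from the
  $\sigma$ coordinate), so the acceptance ratio involves only the data
  likelihood and the hyper-prior. These moves are what brings the
  slope-SD parameters from effective sample sizes of a few dozen to
  several hundred per thousand draws.

Warmup adaptation uses a Robbins–Monro decay ($\gamma_t \propto
t^{-0.6}$); adaptation stops at the end of warmup so the post-warmup
chain is a fixed Markov kernel. Chains must have distinct seeds (a
guard rejects duplicated seeds, which would silently produce identical
chains and meaningless diagnostics).

Convergence is gated quantitatively, since the original visual
inspection cannot be automated: split-chain rank-normalised
$\widehat R \le 1.01$ and bulk ESS $\ge 400$ on every free
hyperparameter, computed from FFT autocovariances with Geyer's initial
monotone positive-sequence truncation. A failed gate is an error unless
`force = TRUE` turns it into a warning. The implementation was checked
against an independent reference implementation on shared fixtures
(agreement to ~4 significant digits on ESS, ~1e-4 on $\widehat R$).
Default sampling (4 chains × 4000 draws after 1500 warmup) clears the
gate with margin on data of the study's size; because the gate sits
near the Monte-Carlo noise floor of $\widehat R$, occasional marginal
failures (e.g. 1.011) remain possible on unlucky seeds, which is
exactly what the gate is for.

## Derived quantities

* **Group comparison**: the posterior of the virus-free minus infected
  difference is formed draw-wise, and the exceedance probability
  P(infected > virus-free) is the fraction of aligned draws with the
  infected value larger, ties counting one half. Exceedance and reverse
  exceedance always sum to one.
* **Personality scores**: each individual's posterior-mean $a_i$, $b_i$,
  $c_i$, $d_i$ — partially pooled estimates that shrink toward the group
  mean, strictly so for extreme individuals. Sex disaggregation is
  post-hoc (the fit itself carries no sex terms), splitting scores into
  the four group × sex strata and counting, per stratum, individuals
  whose latency trend is positive.
* **Prediction curves** plug the hyper-means into the linear predictors
  per draw and report pointwise means with equal-tailed 95 % intervals.
  This is the population-typical curve, not the
  heterogeneity-integrated one; the marginal stay probability
  $E[\mathrm{logit}^{-1}(Z)]$, $Z \sim \mathcal N(\mu_a, \sigma_a^2)$,
  is exposed separately (`marginal_stay_probability()`, adaptive
  quadrature at relative tolerance 1e-8, cross-checked by Monte Carlo).
  At the published group hyperparameters the marginal stay probabilities
  come out near 0.68 (infected) versus 0.19 (virus-free) — the roughly
  four-fold difference in the probability of not emerging.

## Posterior predictive checks

Replicates are generated at the observed design — same individuals,
same trial indices, same centring — conditioning on each selected
draw's individual effects (a within-sample check of fit to the observed
animals, not a new-individual prediction). Built-in statistics probe
both hurdle parts: stay fraction; mean, SD and skewness of observed
latencies; the fraction of latencies above 300 s; and the record count.
The Bayesian p-value convention is $P(T^{\mathrm{rep}} \ge
T^{\mathrm{obs}})$; replicates on which a statistic is not computable
(e.g. an SD with fewer than two emergences) are skipped and counted. On
self-simulated data the latency-mean p-value is central in at least 90 %
of runs; on data with exponential (strongly right-skewed) latencies the
skewness statistic is driven to an extreme p-value — the
gamma-versus-gaussian adequacy question the checks exist to answer.

## The synthetic-data generator

The generator states the study's world and is the package's test bed:
50 virus-free (26 M, 24 F) and 37 infected (19 M, 18 F) individuals,
7–10 trials each (default fixed at 8, the midpoint), a 600 s window with
latencies recorded in \[1, 599\], and the published group posterior
means as the default generating hyperparameters. Latencies are drawn
from the individual's gaussian law, truncated to \[1, 599\] by rejection
and rounded to whole seconds — what an observer with a stopwatch and a
10-minute cutoff would write down. Two values the publication does not
state were fixed once: the residual latency SD (60 s, an
order-of-magnitude choice treated as a free truth parameter by the
recovery tests) and the per-trial mortality hazard of infected animals
(default 0; when enabled, a geometric per-trial hazard with same-sex
replacement individuals under fresh identities, mirroring the study's
replacement protocol).

What a green parameter-recovery test establishes is therefore: data
generated from the stated hierarchy, at the study's sample sizes, let
the sampler recover the generating hyperparameters with approximately
nominal credible-interval coverage (each of the 16 group
hyperparameters is covered in at least 6 of 8 replicates, and the
direction and ordering of the group contrasts is recovered in all). What
it does not establish: anything about features the generator lacks —
intercept–slope correlation, per-group residual spread, non-gaussian
latency shapes, or real mortality dynamics.

One known and deliberate mismatch: the generator truncates and rounds
latencies while the likelihood is untruncated. The resulting ~2–3 s
downward bias in the fitted residual SD is invisible at the scale of
the behavioural parameters but is resolvable by the residual SD's own
narrow posterior (±2 s at the full design), so the *residual SD* is not
held to the coverage criterion — the 16 behavioural hyperparameters
are.

## Numerical choices and degenerate inputs

* Bernoulli log-likelihoods use a stable `log1p(exp(·))` evaluation.
* A `sigma_*` fixed at 0 clamps its effects to the (then required to be
  fixed) hyper-mean — the degenerate-variance limit used by the
  grid-oracle fixture, in which only two parameters remain free and the
  MCMC can be compared against dense 1-D quadrature.
* Exceedance ties count 0.5, so identical groups give exactly 0.5 and
  the exceedance/reverse-exceedance identity holds with ties present.
* 95 % intervals are equal-tailed posterior quantiles throughout.
* Latency exactly at or beyond the 600 s window is not a latency: such
  trials are recorded as not emerged. The validator enforces \[1, 599\].
* Missing sex is tolerated everywhere except sex disaggregation, which
  names the offending individuals.

## Limitations

* Runtime scales linearly in records × iterations; the pure-R sampler
  handles the study design (≈700 records) in well under a minute per
  four-chain fit, but is not built for designs orders of magnitude
  larger.
* Post-hoc sex disaggregation cannot separate sex effects from
  individual effects the way a refit with sex terms could.
* The model has exactly two covariates (group via the hierarchy,
  experience via the slope); no other covariates, no model comparison
  machinery (WAIC/LOO), and no gamma-hurdle variant are provided.
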