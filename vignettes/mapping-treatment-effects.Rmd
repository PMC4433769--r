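---
title: "Synthesising treatment effects across outcome scales by mapping ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesising treatment effects across outcome scales by mapping ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Trials of treatments for conditions such as social anxiety report
"the same" clinical outcome on many different rating scales: one trial
reports the 144-point LSAS, another the 7-point clinician-rated CGI-S,
a third both plus a disability score.  The common workaround —
standardising each mean difference by its sample SD and pooling the
resulting Cohen's-d values — assumes that all instruments are equally
responsive to treatment and that sample SDs estimate a common
population dispersion.  Both assumptions fail in practice: baseline
SDs differ several-fold across trial populations, and instruments with
different item content and reliability cannot be equally sensitive.

`mapmeta` implements the alternative: a joint Bayesian model that pools
the treatment effect on a *reference* instrument while simultaneously
estimating multiplicative **mapping ratios** between the true effects on
different instruments, using every reported outcome from every trial.
Effects can then be read off on any instrument in the network, in that
instrument's own units.

## Model

Index trials by $i$, active arms by $a$ and instruments by $k$, with
$k = 1$ the reference.  Each active arm's true effect on the reference
scale is exchangeable across trials,

$$\delta_{ia} \sim \mathrm{N}(\mu, \sigma^2),$$

with one independent draw per active arm (multi-arm trials draw
$M - 1$ effects from the same distribution; their dependence enters
only through the observation covariance below).  The true effect on
instrument $k$ in trial $i$ is a multiple of the reference effect:

* **fixed mapping**: $\theta_{iak} = \beta_{1 \to k}\,\delta_{ia}$,
  the same ratio in every trial;
* **random mapping**: $\theta_{iak} = \beta_{i,1 \to k}\,\delta_{ia}$
  with $\beta_{i,1 \to k} \sim \mathrm{N}\!\big(\beta_{1 \to k},
  (\varphi\,|\beta_{1 \to k}|)^2\big)$ — ratios vary between trials
  with a constant coefficient of variation $\varphi$;
* **ratios = 1**: $\theta_{iak} = \delta_{ia}$ for every $k$, the
  constraint implicit in pooling standardised effects, used to test
  equal responsiveness.

Ratios are transitive, so with $M$ instruments only the $M - 1$ basic
parameters $\beta_{1 \to k}$ are estimated;
`derived_mapping()` returns any other pair's ratio as
$\beta_{h \to k} = \beta_{1 \to k} / \beta_{1 \to h}$.  All five model
variants reported by `fit_report()` are combinations of these three
structures with raw or standardised (`standardise_dataset()`) effects.

The observed mean differences in a trial form one multivariate-normal
vector around the $\theta$'s.  Trials rarely publish within-trial
correlations, so the covariance is reconstructed
(`trial_covariance()`) from the reported standard errors, pooled SDs,
arm sizes, and a single between-instrument score correlation $\rho$:

* same arm, instruments $h \ne k$: $\rho\,se_h\,se_k$;
* different arms, same instrument (shared control arm):
  $sd_h^2 / n_{\mathrm{control}}$;
* different arms, different instruments:
  $\rho\,sd_h\,sd_k / n_{\mathrm{control}}$.

The default $\rho = 0.65$ comes from the psychometric literature on
social-anxiety measures; `rho_sensitivity()` refits at 0.55 and 0.75.
Every matrix is validated by Cholesky factorisation, so inconsistent
se/SD/n inputs fail loudly rather than silently distorting the fit.

## Priors and numerical choices

The prior layer is deliberately vague on the data scale:
$\mu \sim \mathrm{N}(0, 100^2)$, each
$\beta_{1 \to k} \sim \mathrm{N}(0, 100^2)$, $\varphi \sim
\mathrm{U}(0, 2)$, and a uniform prior for the between-trials
dispersion bounded at 50 raw points (5 for standardised effects).  The
uniform is placed on the **variance** scale by default
(`prior_spec(sigma_prior = "uniform_var")`), i.e. a density
proportional to $\sigma$ on the SD scale; `"uniform_sd"` is the
alternative, and the posterior median of $\sigma$ moves by roughly
5–8% between the two on the packaged data — a useful reminder that
with 22 trials the heterogeneity parameter is prior-sensitive.  The
random-mapping hierarchy defaults to the natural scale above;
`model_spec(ratio_scale = "log")` instead draws trial ratios lognormal
with log-SD $\varphi$, which constrains them positive and gives an
equivalent CV for small $\varphi$.

Degenerate corners are guarded explicitly: the hierarchical SD
$\varphi\,|\beta|$ is floored at machine epsilon so $\varphi \to 0$ or
a sign-crossing $\beta$ proposal cannot produce infinite densities,
and out-of-support states return $-\infty$ from `log_prior()` rather
than raising errors.

## Sampling

`run_mcmc()` runs an adaptive Metropolis-within-Gibbs sampler
(RcppArmadillo core): one scalar random-walk block per parameter
($\mu$, $\log\sigma$, each $\beta_{1 \to k}$, $\log\varphi$, each
$\delta_{ia}$, each trial ratio), plus — in the random-mapping variant
— a joint translation block per instrument that moves
$\beta_{1 \to k}$ and all its trial ratios together.  The joint block
matters when $\varphi$ is small: the trial ratios are then tethered
tightly to their mean, and single-site updates crawl along the
resulting ridge, whereas the joint move leaves the hierarchical
residuals invariant and mixes freely (this is also what makes the
random model collapse cleanly onto the fixed model as
$\varphi \to 0$).

Proposal scales start at data-informed values (roughly the inverse
root of each block's summed likelihood precision), adapt in batches
toward 44% acceptance during burn-in only, and are frozen afterwards,
preserving detailed balance for the retained draws.  Chains start from
overdispersed, data-informed values; starting values respect the sign
structure identified by the reference-scale observations, because the
sign-reflected basin $(\delta > 0, \beta < 0)$ is separated from the
data-supported one by a likelihood barrier that coordinatewise
proposals cannot cross.  All randomness flows from the single
configuration seed, so runs are bit-reproducible.

Defaults are four chains of 20,000 kept draws after 30,000 burn-in
iterations (about 4 s per chain on the packaged data); the worked
analyses in the tests use four chains of 5,000 + 5,000, which already
hold Monte-Carlo error well below the reporting precision.
Convergence is monitored by split-chain $\widehat{R}$
(`gelman_rubin()`), with a reporting gate at 1.05.  Model fit is
summarised by the posterior mean residual deviance
(`residual_deviance()`), which for a well-fitting model is close to
the number of observations (88 here); it is recomputed from the stored
draws rather than read from sampler bookkeeping, and the two paths are
cross-checked in the tests.

## The synthetic-data generator

`simulate_dataset()` generates whole trial networks in the generative
direction of the model: per-arm effects from
$\mathrm{N}(\mu, \sigma^2)$, ratios fixed or drawn with CV $\varphi$,
trial-level SDs lognormal around per-instrument typical values
(matching the several-fold variance spread seen in the real data), arm
sizes uniform on 30–200, and observation noise drawn with exactly the
covariance that `trial_covariance()` reconstructs — standard errors
are derived from the simulated SDs and arm sizes
($se^2 = sd^2(1/n_c + 1/n_a)$) precisely so that the Monte-Carlo
covariance oracle in the test suite is exact rather than approximate.
Trial designs mirror the packaged network (22 trials, mostly two-arm,
one to six instruments each, the reference reported with probability
0.8); disconnected draws are repaired by adding the reference
instrument to one trial of each stranded component.

What the generator does **not** emulate: extraction error, selective
outcome reporting, follow-up versus change-from-baseline mixtures,
non-normal outcome distributions, and correlation between a trial's
effect size and its design.  Passing parameter-recovery tests
(`recovery_experiment()`: near-zero bias and near-nominal credible
coverage for $\mu$ across replicates) therefore validates the
estimation machinery under the model's own assumptions, not robustness
to real-data pathologies.

## Classical companions

`bartlett_sd_test()` applies Bartlett's homogeneity test to the
per-trial pooled SDs of one instrument (summary-statistic form, since
raw data are unavailable), and `pooled_within_sd()` gives the
df-weighted pooled SD.  The degrees of freedom attached to a pooled SD
are a convention; `variance_samples()` defaults to the number of
active-arm patients per trial, which reproduces the published analysis
of this evidence base, and offers total-randomised-minus-arms as the
textbook alternative.  On the packaged LSAS SDs (16.1 to 35.5, a
near-fivefold variance range) either convention rejects homogeneity
overwhelmingly ($\chi^2_{18} \approx 279$ or $\approx 495$), which is
the empirical core of the argument against sample-SD standardisation.

## Known limitations

* The random-mapping model is not invariant to the choice of reference
  instrument (the fixed-mapping likelihood is, and the tests verify
  it); reference-change sensitivity should be checked when ratios are
  of substantive interest.
* $\rho$ is a single external constant for all instrument pairs, not
  estimated from data.
* With few trials per instrument pair, $\sigma$ and $\varphi$ are
  prior-sensitive (see the `sigma_prior` knob); report both settings
  when the distinction matters.
* Standardised-effect analyses divide the reported standard error by
  the pooled SD.  Pipelines that instead recompute the classical SMD
  variance $1/n_c + 1/n_a + d^2/2N$ will give slightly different
  dispersion summaries and residual deviances (a few points out of
  ~200 on the packaged data).
* Observations enter as mean differences against a shared control;
  arm-level entry (which diagonalises the between-arm covariance) is
  not implemented.

## A worked run

```{r, eval = FALSE}
library(mapmeta)
ds <- social_anxiety_data()
instrument_network(ds)

fit <- run_mcmc(model_spec("random_mapping"), ds,
                mcmc_config(n_burn = 5000, n_keep = 5000, seed = 1))
summary(fit)            # mu, sigma, mapping ratios, phi, deviance
map_pooled_effects(fit) # the pooled effect on all nine instruments
```
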