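---
title: "Methods: hierarchical diffusion modelling with EEG slope coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical diffusion modelling with EEG slope coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(driftslope)
```

This vignette documents the models and algorithms in `driftslope`, the
assumptions behind them, and the design choices made where more than one
reasonable implementation existed.

## The decision model

Behaviour in a two-choice global-motion task (left/right judgements under a
2.5 s response deadline) is modelled with the Wiener diffusion process.
Evidence accumulates from a starting point `z = z_rel * a` at drift-rate `v`
with within-trial noise SD `s` until it reaches the upper bound (`a`, the
right response) or the lower bound (0, left). Observed RT is the first
passage time plus a non-decision time `ter` covering encoding and motor
execution. `s` is fixed at 0.1 — the conventional resolution of the model's
scaling degeneracy; all evidence-unit parameters are interpreted on that
scale.

Drift is stimulus-coded: a rightward stimulus drives the process at `+v`,
a leftward one at `-v`, and `z_rel` is a response bias toward the right
bound. Each participant has five parameters: boundary separation `a`,
relative start point `z`, non-decision time `ter`, and drift-rates for the
easy and difficult levels, parameterised as the average `v.mean = (v1 +
v2) / 2` and the difference `v.diff = v1 - v2` (level 1 is the easy level,
so `v.diff` is expected positive; the printed model does not fix that
order, and the choice only relabels the sign of `v.diff`).

Two model features matter for the data at hand:

* **Non-responses.** Trials with no response before the 2.5 s deadline are
  treated as non-terminating accumulation trajectories: their likelihood is
  the survivor function `S(deadline) = 1 - F_upper - F_lower`, evaluated at
  the deadline on the total-RT clock. The generator uses the same
  convention (a trial times out when `ter` + decision time > 2.5 s).
* **Fast guesses.** Responded trials faster than 200 ms are removed before
  fitting (`filter_trials()`), with per-group exclusion percentages
  reported. Catch trials (maximal-coherence probes inserted to keep
  children engaged) are excluded from the likelihood; this is configurable,
  as the original description is silent about them.

### Numerical evaluation

The first-passage density uses the dual series representation, choosing
between the small-time and large-time expansions by their required term
counts at each evaluation. The defective CDF integrates the large-time
series term by term (with a sign-independent envelope as the stopping
rule, since the `sin(k*pi*w)` factors vanish at even `k` for unbiased
starting points) and falls back to 64-node Gauss-Legendre quadrature of
the density when the scaled decision time is below 0.02. Both agree with
direct quadrature to ~1e-10 and with a million-trial stochastic oracle to
Kolmogorov distance < 0.01.

A responded trial at `rt <= ter` has zero density. Its log-likelihood is
set to a finite penalty (default `-1e10`, configurable) rather than
`-Inf`, keeping Metropolis arithmetic well defined while making such
states effectively impossible.

The trial simulator integrates the SDE by Euler-Maruyama (`dt` = 0.1 ms)
with a Brownian-bridge correction for crossings between grid points,
removing the leading discretisation bias.

## The hierarchy and the group-difference parameterisation

Each subject parameter is drawn from a group-level distribution with three
hyperparameters: population mean `mu`, SD `sigma`, and a symmetric group
offset `delta`, with location `mu + delta` for the dyslexia group and
`mu - delta` for the typical group. Negative `delta` therefore means lower
values in the dyslexia group, and the difference between group means is
`2 * delta`; what the package reports as the "group difference" is `delta`
itself, matching how these posteriors are usually plotted. `a` and `ter`
use positive-truncated normal group distributions and `z` a normal
truncated to (0, 1), all with normalisation constants included; `v.diff`
and `v.mean` are unbounded normals.

Hyperpriors (`default_priors()`):

* `mu_a ~ N+(0.2, 0.2)`, `mu_z ~ TN[0,1](0.5, 0.2)`,
  `mu_ter ~ N+(0.3, 0.3)`, `mu_v.diff ~ N(0, 0.1)`,
  `mu_v.mean ~ N(0.3, 0.3)`
* every `sigma ~ Gamma(1, 1)` (shape/rate, i.e. Exponential(1))
* every `delta ~ N(0, 0.01)`

The second argument of every (truncated) normal is read as a standard
deviation, consistently across the listing. For the `delta` priors the
alternative variance reading (SD 0.1) cannot be ruled out from the
notation alone; SD is the default here because the same notation plainly
means SD for the `mu` priors, and because `N(0, 0.01)` as an SD matches
the "moderately informative" role these priors play. Savage-Dickey Bayes
factors are directly sensitive to this scale, so it is exposed
(`default_priors(delta_sd = )`) rather than buried.

### Age adjustment

Group differences can be confounded with age. Two strategies are
implemented (`partial_out_age()`), because the original "residuals from
the line of best fit" description is ambiguous between them:

* **covariate** (default): group locations become
  `mu + c * delta + beta_age * (age - mean(age))` with
  `beta_age ~ N(0, 0.5)` per parameter, estimated jointly. When all ages
  are equal this reduces exactly to the unadjusted model.
* **two_stage**: fit the unadjusted model, regress subject-level posterior
  means on age, and fit a small normal `mu ± delta, sigma` model to the
  residuals.

Both produce a `delta` posterior per parameter; neither is asserted to be
the original mechanics.

## The sampler

The posterior is sampled with blocked differential-evolution MCMC. Each
iteration sweeps: every participant's 5-parameter block (conditional on
the hyperparameters), then each hyperparameter triple `(mu, sigma, delta)`
as a 3-dimensional block, then (when present) age slopes, EEG
hyperparameter triples, and the correlation parameters. A chain's proposal
for a block is `x + gamma * (x_r1 - x_r2) + eps` using two other randomly
chosen chains from the current ensemble; because the donor pair is
unordered, the marginal proposal is symmetric and plain Metropolis
acceptance applies. Tuning follows the standard DE-MCMC recommendations
(not printed in the source description): `gamma = 2.38 / sqrt(2d)` per
block with probability 0.1 of `gamma = 1` (mode jumping), and
`eps ~ U(-0.001, 0.001)`.

Defaults for the behavioural model are 15 chains, 4000 iterations, 1500
burn-in, with migration every 14 iterations between iterations 500 and
1100: a random subset of chains (size uniform on 1..n_chains) proposes a
cyclic hand-me-down of states, each swap accepted by its own Metropolis
ratio, never forced. The joint model uses 3000 iterations, 1000 burn-in
and no migration. Proposals outside a parameter's support are rejected via
a `-Inf` target, so stored draws always respect the supports. Convergence
is monitored with the classical (unsplit) Gelman-Rubin statistic, floored
at 1.

Initialisation draws from the priors, with two pragmatic exceptions.
First, each participant's non-decision time starts below their fastest
response: with 20+ participants, at least one pure prior draw would
exceed someone's fastest RT almost surely, stranding that likelihood at
the penalty floor before sampling begins. Second, in the joint model the
EEG population location and scale start moment-matched to the observed
slopes: without migration, a chain whose EEG location starts several
prior SDs off the data scale can stall for an entire run. Participants
whose likelihood is still not finite after 100 redraws abort with an
error naming them.

## Group-difference evidence

`savage_dickey()` computes BF10 for the point null `delta = 0` as the
prior density at zero over the posterior density at zero. The posterior
density is a Gaussian kernel estimate with Silverman's bandwidth; a
normal-approximation estimate is always computed as a cross-check, and a
discrepancy above 0.5 log units raises a warning (the density method used
originally is unstated; the KDE is robust at the sample sizes involved
and the cross-check makes its influence visible). Bayes factors between
1/3 and 3 are conventionally read as weak, inconclusive evidence.
`effect_size()` reports the standardised population effect `delta /
sigma` draw by draw, with a central 95% credible interval — the central
interval matches the usual reporting style. `defective_quantiles()`
summarises RT distributions as nine decile points per group x difficulty
x correctness cell, scaled by response probability, with the timeout mass
at the deadline; `posterior_predict()` generates the model-predicted
counterpart.

## From continuous EEG to the pre-response slope

The EEG measure entering the joint model is the build-up rate of a
centro-parietal component in the 200 ms before the response. The pipeline:

1. **Epoch and baseline** (`epoch_and_baseline()`): response-locked
   epochs, -600..200 ms at 250 Hz, baselined per trial to the last 100 ms
   of the pre-stimulus random-motion period (the 100 ms before the
   stimulus onset the response belongs to).
2. **Reliable Components Analysis** (`rca_fit()`): spatial filters
   maximise across-trial reliability via a generalized eigendecomposition
   of the mean cross-trial covariance against the mean within-trial
   covariance (solved by whitening; diagonal loading with a warning if the
   within-trial covariance is rank deficient). Components are ordered by
   reliability; forward projections map the filters through the pooled
   covariance, and signs are fixed so each projection's dominant entry is
   positive. Continuous data are projected through the leading component's
   weights (`rca_project()`).
3. **FIR time expansion** (`build_design()`): one boxcar predictor per
   (event type x difficulty x lag) on a half-open lag window [-1000,
   1000) ms at 4 ms steps — exactly 500 lags per condition at 250 Hz; the
   closed interval would give 501. Catch-trial events are treated as easy
   (they are maximal-coherence stimuli of the same kind).
4. **Artifact masking** (`mask_artifacts()`): any sliding 2000 ms segment
   (100 ms steps) containing an excursion beyond ±250 µV is excluded
   wholesale from the fit, with the excluded fraction reported. The mask is
   applied to the component waveform, which is what gets deconvolved.
5. **Ridge deconvolution** (`deconvolve()`): `beta = argmin ||y - X
   beta||² + lambda ||beta||²`; `lambda = 0` is OLS, and a singular OLS
   system produces an error directing to the ridge path. `select_lambda()`
   cross-validates `lambda` per participant over 5 contiguous time-segment
   folds on a 0..30 grid in 0.5 steps (reported per-participant means like
   5.5 imply a half-step grid; fold structure was unstated, and contiguous
   segments respect the autocorrelation of EEG), then applies the **mode**
   across participants to everyone — one common penalty per task, so
   regularisation differences cannot masquerade as group differences.
   Ties resolve to the smaller penalty.
6. **Slope extraction** (`extract_slopes()`): an OLS line through the
   response-locked deconvolved waveform between -200 and 0 ms (inclusive,
   at the native 250 Hz — no resampling), in µV/s, per difficulty.
   `eeg_mean` is the mean of the two slopes, `eeg_diff` their difference
   (easy - hard), mirroring the drift parameterisation.

## The joint model

The joint model replaces the univariate population terms for `v.diff` and
`v.mean` with bivariate normals pairing them with the observed EEG
measures: `(v.diff, EEG.diff)` and `(v.mean, EEG.mean)`, each with means
`mu ± delta` per the group convention and covariance built from the
marginal SDs and a correlation. EEG hyperpriors are `mu_EEG.diff ~ N(0,
0.5)`, `mu_EEG.mean ~ N(0, 1)`, `sigma ~ Gamma(1, 1)`, `delta ~ N(0,
0.01)`, and `rho ~ U(-1, 1)`. The slope measures are fixed observed data
(no measurement-error model). There is one correlation per pair
(`rho_mean`, `rho_diff`), each either shared across groups or
group-specific (`variant = "group_rho"`). `rho` blocks update with
reflecting boundaries at ±1, which preserves proposal symmetry. The
Savage-Dickey numerator for `rho = 0` is the exact uniform density, 0.5.
Participants with behavioural data but no EEG contribute through the
univariate marginals of the bivariate terms — i.e. exactly their ordinary
group-model terms; how the original analysis handled them is unknown, and
marginalisation is the choice here.

## The synthetic world

`simulate_behaviour()` reproduces the experimental design: two tasks, four
experimental blocks per task, each with 9 repetitions of 2 difficulty
levels x 2 directions plus 2 catch trials — 38 trials per block, 152 per
task — a 2.5 s deadline producing genuine non-responses, and end-of-block
points `round(2 * n_correct / median RT)` floored at 10. Trial timing
(fixation, random-motion, offset periods) is jittered uniformly within
1.0-1.5 s, 1.0-1.5 s and 0.25-0.5 s; the original ranges are not
reported, and these placeholders matter only through the event spacing
they induce for deconvolution. All randomness flows from one root seed
through per-participant substreams.

Planted truth defaults (`generator_config()`) were chosen once to match
the reported flavour of the data — easy-level accuracy near ceiling,
difficult-level accuracy near 0.8, median RTs around 0.6 s, and roughly 1%
of trials timing out: `mu = (a 0.15, z 0.5, ter 0.3 s, v.diff 0.15,
v.mean 0.2)` with SDs `(0.03, 0.05, 0.05, 0.05, 0.05)` and `delta = 0`.

`simulate_eeg()` builds continuous component-space EEG as the sum of a
stimulus-locked half-sine burst (0-600 ms, amplitude larger for easy
stimuli) and a response-locked linear ramp over the 400 ms before each
response, plus stationary AR(1) noise (coefficient 0.95, SD 10 µV at 250
Hz). The ramp's slope is the participant's planted slope, generated by the
linear link `slope_d = alpha0 + alpha1 * v_d + e`; the residual SD is
derived so that the population correlation between `v.mean` and the
planted `EEG.mean` equals `rho_target` (0.44 by default), and the link
scale (`alpha0 = 0.5`, `alpha1 = 8` µV/s per drift unit) keeps the slopes
on the O(1) scale the joint model's EEG priors describe. Timeout trials
contribute no response event — exactly the censoring structure the
deconvolution must cope with. Optional multichannel output projects the
component through a planted topography with independent channel noise,
which is what the RCA stage recovers.

What the generator does *not* emulate: real scalp EEG's 1/f and
oscillatory structure, eye/muscle artifacts, drifting electrode
impedances, or any nonlinearity in the drift-EEG relation. Passing tests
therefore demonstrate that the estimators recover the truth of *this*
generative world (overlapping kernels, AR(1) noise, linear link), not that
the preprocessing of real recordings is handled — the upstream cleaning
chain (filtering, artifact-subspace reconstruction, ICA) is explicitly out
of scope, and real-data ingestion assumes already-clean signals.

## Problem sizes used by the test suite

The validation suite runs the full method at reduced but honest sizes,
chosen as the smallest studies at which each property is clearly
expressed: likelihood checks against a 10^6-trial simulation oracle;
sampler checks against conjugate closed forms; a main recovery study of 2
groups x 12 participants x 152 trials at 15 chains x 1500 iterations; ten
replicate fits of 2 x 12 participants (shortened chains) for the sign of a planted
`delta_v.mean = -0.02`; and ten replicate joint fits of 2 x 25
participants (one block each) at 15 chains x 1000 iterations for coverage
of the planted correlation 0.44. `scripts/acceptance.R` re-runs the same
computations from scratch and writes the headline numbers as JSON.

## Known limitations

* The likelihood has no trial-to-trial variability parameters (`sv`,
  `st0`, `sz`) — deliberately, matching the model it implements.
* `delta`-prior scale ambiguity (SD vs variance) propagates directly into
  Bayes factors; both readings are one argument away.
* The two-stage age adjustment ignores the uncertainty of the first-stage
  posterior means; the covariate variant is the default for that reason.
* DE-MCMC with 15 chains explores the 5-per-subject-block geometry well at
  these sizes, but very small `sigma` draws can make subject blocks
  sticky; acceptance rates are reported per block type so this is visible.
* The EEG pipeline assumes events snap to the 250 Hz grid; sub-sample
  event timing is not modelled.
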