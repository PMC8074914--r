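---
title: "Models and methods behind alloctrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alloctrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

People dislike unequal allocations, but "inequality aversion" conflates two
separable concerns: an *egalitarian* concern about the dispersion (variance,
or Gini coefficient) of pay-offs, and a *maximin* concern for the worst-off
recipient's pay-off. alloctrace implements a complete analysis chain for a
third-party allocation task designed to separate the two: on each trial a
decision maker chooses between a **Utilitarian option** (larger total
pay-off across three recipients) and a **non-Utilitarian option** (higher
minimum pay-off *and* lower Gini coefficient, but smaller total). Choices
reveal the overall preference; the mouse cursor's path while deciding,
sampled at 60 Hz, reveals *when* each concern starts to pull.

Two questions structure the analysis:

1. **Behavioural:** are choices better explained by a utility model built on
   the minimum pay-off or one built on the variance?
2. **Cognitive:** at which moment of the decision does each attribute begin
   to steer the cursor, and which dominates?

## Utility models for choices

For an allocation $x = (\pi_1, \pi_2, \pi_3)$:

* **Quasi-maximin (model A):**
  $U_i(x) = \alpha_i \min(\pi) + (1 - \alpha_i)\sum \pi$, with
  $\alpha_i \in [0, 1]$ the participant's concern for the minimum.
* **Mean-variance (model B):**
  $U_i(x) = \tfrac{1}{3}\sum \pi - \beta_i \,\mathrm{Var}(\pi)$, with
  $\beta_i$ unconstrained; larger $\beta_i$ means stronger variance
  aversion. The variance is the population variance (divisor $n = 3$), the
  convention of the mean-variance tradition; a `divisor` argument exposes
  the $n-1$ alternative.

Choices follow a logistic (softmax) rule on the utility difference,
$P(\text{choose } N) = \mathrm{logit}^{-1}\!\big(\tau_i\,[U_i(N) -
U_i(U)]\big)$, with a participant-specific inverse temperature $\tau_i > 0$.
Utilities are rescaled to 100-yen units inside the likelihood so that
$\tau_i$ and $\beta_i$ are order one; this is a pure reparameterization
(an order-one $\beta$ on the scaled utilities equals $\beta/100$ on the yen
scale, which the test suite checks explicitly).

Two fitting modes are provided, because the hierarchical structure of the
original specification of this task family is not fully pinned down:

* **hierarchical** (default): $\mathrm{logit}(\alpha_i)$, $\beta_i$ and
  $\log \tau_i$ are drawn from population normal distributions, sampled with
  a non-centered parameterization (the centered form mixes visibly worse
  here: weakly informed participants create a funnel).
* **independent**: fixed priors per participant —
  $\alpha_i \sim \mathrm{Beta}(1,1)$ (non-informative),
  $\beta_i \sim N(0,1)$ (informative on the scaled utilities, where order-one
  values span indifference to strong variance aversion), and
  $\log\tau_i \sim N(0,1)$.

Sampling uses JAGS; split-$\hat R$ is computed for every monitored
parameter and a fit is flagged non-converged when any reaches 1.1. A
prior-sensitivity runner (`prior_sensitivity()`) refits under alternative
prior settings to reproduce the usual robustness check that posterior means
and model ranking are stable across reasonable priors.

## Marginal likelihoods and the Bayes factor

Model comparison uses the Bayes factor
$\mathrm{BF}_{AB} = p(y \mid A)/p(y \mid B)$. The package computes log
marginal likelihoods two ways:

* **Bridge sampling** (`bridge_logml()`): the iterative optimal-bridge
  estimator with a moment-matched multivariate normal proposal on the
  unconstrained parameter space. Half of the posterior draws fit the
  proposal, the other half enter the bridge, which guards against the
  known optimistic bias of reusing all draws. The log posterior is written
  out exactly (normalized priors, transform Jacobians), so the estimate
  targets the true marginal likelihood, not an arbitrary constant multiple.
* **Adaptive 2-D quadrature** (`quadrature_oracle_logml()`): for a single
  participant under independent-mode priors the marginal likelihood is a
  2-D integral over (preference parameter, $\log\tau$). The mean-variance
  likelihood is a near-threshold function of $\beta$ whose informative
  width shrinks like $1/\tau$, so a fixed-order rule over the prior box
  fails; instead a coarse scan localizes the mass-carrying $\beta$ range
  *per $\tau$ node* and Gauss–Legendre rules are placed on those ranges.
  Two resolutions are compared and an error is raised if they disagree
  beyond $10^{-4}$ nats. A deliberately crude dense midpoint grid
  (`grid_logml()`) validates the adaptive rule.

The two routes are kept strictly independent so each can falsify the other;
their agreement (within 0.05 nats on single-participant fits) is part of
the acceptance surface. For sweeps over many synthetic datasets the
independent-mode quadrature marginal likelihood (a sum over participants)
gives a deterministic, MCMC-free Bayes factor; the hierarchical
bridge-sampled version is computed for the headline comparison.

## Trajectory preprocessing

Raw cursor samples arrive in pixels with y growing downward. An affine map
fixed by three anchors — start button $\to (0,0)$, left target
$\to (-1,1)$, right target $\to (1,1)$ — carries paths into the analysis
frame; the anchor correspondence absorbs the y flip, so no sign conventions
appear anywhere else. The x coordinate is then negated on trials where the
non-Utilitarian option sat on the left, making positive x mean "toward the
non-Utilitarian option" on every trial.

Every trial is linearly interpolated against time onto 101 equally spaced
bins from trial onset to the click, so trials of different durations are
comparable; bin 1 and bin 101 reproduce the first and last samples exactly.
Linear interpolation is the standard choice for this normalization and
cannot overshoot the data's range; because the coordinate map is affine and
the interpolant linear, normalizing before or after the coordinate map
yields identical results, so the order is irrelevant. There is no trial
exclusion rule anywhere: all trials enter every analysis.

## The trajectory state-space model

The core model asks, for every normalized time bin $t = 1,\dots,101$, how
strongly the standardized between-option differences steer the cursor. With
$x_{t,i,j}$ the oriented x position of participant $i$ on trial $j$:

$$x_{t,i,j} = \mu_{t,i} + \beta^{\min}_{t,i} D^{\min}_j +
  \beta^{\mathrm{var}}_{t,i} D^{\mathrm{var}}_j + \varepsilon, \qquad
  \varepsilon \sim N(0, 0.005),$$

where $D^{\min}_j$ and $D^{\mathrm{var}}_j$ are the absolute between-option
differences in minimum pay-off and Gini coefficient, standardized to mean
zero and unit variance across the problem set so the two coefficient series
are comparable in magnitude. Participant coefficients scatter normally
around population series, and the population series evolve as Gaussian
random walks pinned to zero at $t = 1$ (the cursor always starts at the
origin, so nothing can be predicted there). All $N(\cdot,\cdot)$ scale
arguments are standard deviations — the convention of the estimation stack
this model family is usually written in — so the observation noise SD is
0.005 by default (configurable).

Interpretation: the first bin at which the pointwise 95% HDI of a
population series excludes zero is the moment that attribute credibly
begins to modulate the cursor; comparing the two series bin by bin (the
HDI of their difference) shows which concern dominates when.

Design choices where the model family leaves room:

* **Intercept dynamics.** The intercept recursion
  $\mu_{t,i} = \mu_{t-1,i} + \delta_i$ with a non-time-indexed $\delta_i$
  literally describes a constant per-participant drift (a linear trend);
  that literal reading is the default (`mu_dynamics = "linear_drift"`),
  with a per-participant random walk selectable. Both modes pass recovery
  tests.
* **Participant-deviation SDs.** A per-bin deviation SD (101 hyperparameters
  per coefficient) is weakly identified with desk-scale data, so one shared
  SD per coefficient is the default (`eta_mode = "shared"`), with
  `"per_time"` selectable.
* **Priors.** Half-normal with unit scale on every SD hyperparameter —
  weak after feature standardization, where plausible coefficient SDs are
  well below one.

**Sampling.** Given the SD hyperparameters the model is entirely
linear-Gaussian, so the sampler is a blocked Gibbs scheme rather than a
generic MCMC engine: exact conjugate draws for the per-(bin, participant)
coefficient pairs (one Cholesky per participant per sweep, shared across
bins), conjugate draws for the drifts, forward-filtering
backward-sampling (FFBS) for the population random walks (and the
random-walk intercepts, vectorized across participants), and univariate
slice updates on $\log\sigma$ for the half-normal SDs. Three chains with
overdispersed SD initializations are run (800 warmup + 600 kept draws by
default); split-$\hat R$ covers every parameter — population series and SDs
from full draws, the ~20,000 participant-level coefficients from
per-half-chain moments — and any value at or above 1.1 flags the fit. The
slice-sampled random-walk innovation SDs are the slowest movers and sized
the default chain lengths.

**Bands.** Pointwise intervals are highest-density intervals (the shortest
window on the sorted draws). The simultaneous band scales the per-bin
posterior SD by the 95th percentile of each joint draw's maximum
standardized absolute deviation across bins, giving $\ge 95\%$ joint
coverage; degenerate bins (the pinned $t=1$) are excluded from the maximum.
The trajectory bands are HDIs (that is what such figures report); scalar
parameter summaries elsewhere in the package use equal-tailed quantile
intervals, the default reporting convention of the hierarchical-GLM stacks
this model family is usually fit with.

## The synthetic experiment generator

The generator exists so that every stage can be exercised, and its
parameters recovered, without any external data. Its defaults *are* the
study conditions; they were fixed once, from the task's published
structure, and are not tuning knobs:

* 36 participants x 48 problems, 60 Hz sampling, 101 bins.
* **Problems:** pay-off triples in the hundreds-to-low-thousands of yen;
  the non-Utilitarian option is a tight triple around a base of 400–700
  yen; the Utilitarian option takes a minimum 120–550 yen lower, a total
  100–500 yen higher, and a Gini gap of 0.04–0.34 *drawn independently of
  the minimum gap* (the gap is hit by solving for the middle pay-off).
  That decoupling brings the natural correlation between the two
  difference predictors down to $\approx 0.59 \pm 0.08$; whole-set
  rejection then enforces the target band $0.49 \pm 0.1$, the moderate
  correlation that characterizes ecologically natural choice sets. Below 5
  problems a sample correlation is too unstable to constrain and the check
  is skipped.
* **Agents:** quasi-maximin with $\alpha \sim N(0.85, 0.1)$ clipped to
  $[0,1]$ and $\tau \sim \mathrm{LogNormal}(\log 0.5,\, 0.6)$, calibrated
  so that roughly 73% of simulated choices are non-Utilitarian — the
  choice split this task family produces. Mean-variance agents
  ($\beta \sim N(0.3, 0.15)$ on scaled utilities) are available for
  model-selection studies. Response times are log-normal
  ($\mathrm{meanlog} = \log 1.8$, $\mathrm{sdlog} = 0.5$; mean
  $\approx 2.0$ s, SD $\approx 1.1$ s).
* **Trajectories** are generated from exactly the state-space process the
  model fits — population series (by default smooth ramps: the minimum
  series rising from bin 29, the Gini series from bin 50), participant
  deviations (SD 0.05), per-participant drift (SD 0.003) and observation
  noise (SD 0.005) — then pinned to the start point at bin 1 and the
  chosen target at bin 101, mapped to pixels and resampled onto the 60 Hz
  clock over the trial's response time.

Because generation equals the fitted model, parameter recovery is a sharp
test of the whole chain: simulate, push through preprocessing (pixels, 60
Hz resampling, re-normalization) and check that the posterior bands cover
the generating series. Two consequences of this design are worth knowing.
First, a zero-coefficient, zero-noise trajectory hovers on the midline and
reaches the chosen target only at the click bin — the generator makes no
attempt at kinematic realism (velocity profiles, submovements are
non-goals). Second, the pinned final bin is choice- rather than
feature-driven, so recovery fits see a contaminated bin near $t = 101$;
coverage criteria are therefore stated over fractions of bins, not every
bin. What passing recovery tests show about real data is correspondingly
limited: they validate the estimator under the model's own assumptions,
not the assumptions themselves (real cursor paths are bounded, autocorrelated
in their innovations, and their predictors collinear in ways the generator
only partially emulates via the 0.49 feature correlation).

## Problem sizes and numerical choices

The test suite runs the full chain at three scales, chosen as the package's
own balance between statistical sharpness and iteration speed: unit and
property tests on 6 participants x 12–16 problems; state-space recovery on
the desk-scale fixture of 10 participants x 16 problems (a step-onset
series at bin 30 must be localized within ±3 bins across seeded
replicates); and choice-model recovery and model selection at the full 36
x 48 across 20 seeded replicates each. Quadrature tolerances are $10^{-4}$
nats internally with a $10^{-3}$ agreement requirement against the dense
grid; bridge sampling iterates to $10^{-10}$ on the log marginal
likelihood. Every random quantity in tests, scripts and the acceptance
runner derives from one integer seed.

## Known limitations

* The exact priors and link function of the original hierarchical
  specification of this task family live in supplementary material not
  reproduced here; the defaults follow the literal model equations and
  standard conventions, and are exposed as configuration rather than
  presented as the authors' certain choices.
* Participant-level $\alpha$ intervals cannot cover agents clipped to
  exactly $\alpha = 1$ (about 7% of draws under the default population);
  pooled interval coverage therefore sits a few points below nominal by
  construction.
* The mean-variance model's marginal likelihood is numerically delicate at
  large $\tau$; the adaptive quadrature handles it, but extremely
  deterministic synthetic participants (hundreds of consistent trials at
  $\tau \gg 10$) can still trip the tolerance check, which errors rather
  than returning a silently wrong value.
* With a truly null coefficient series the random-walk decomposition is
  only weakly identified against a small constant offset: as the
  innovation SD collapses, the population series pools all bins and
  concentrates on the grand mean of the finite sample of participant
  deviations, which is rarely exactly zero. In a minority of null-series
  replicates the resulting narrow band excludes zero over extended
  stretches; the departure detector inherits this (plus the ordinary
  ~5% pointwise false-exclusion rate), which is why departure
  localization is validated on its central (median) behaviour across
  replicates rather than per replicate.
* Y-coordinate modelling, velocity analyses and continuous-time variants
  are out of scope.
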