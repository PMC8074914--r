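# alloctrace

Tools for studying the cognitive basis of inequality aversion in
third-party resource allocation. When people divide money among others
they dislike inequality — but "inequality" conflates two concerns that
pull apart empirically: an **egalitarian** concern about dispersion
(variance / Gini coefficient) and a **maximin** concern for the worst-off
recipient. alloctrace implements the full analysis chain for a
mouse-tracking task that separates them: participants choose between a
*Utilitarian* option (larger total for three recipients) and a
*non-Utilitarian* option (higher minimum pay-off and lower Gini, smaller
total), while the cursor is sampled at 60 Hz.

The package is aimed at decision scientists who want to fit these models
to their own task data or to run fully synthetic recovery studies.

## What it computes

**Choice level.** Two social-preference utility models over allocations
$x = (\pi_1, \pi_2, \pi_3)$:

- quasi-maximin (model A): $U_i(x) = \alpha_i \min(\pi) + (1-\alpha_i)\sum\pi$,
  $\alpha_i \in [0,1]$;
- mean-variance (model B): $U_i(x) = \frac{1}{3}\sum\pi - \beta_i \mathrm{Var}(\pi)$.

Choices follow $P(N) = \mathrm{logit}^{-1}(\tau_i [U_i(N) - U_i(U)])$.
Both models are estimated hierarchically by MCMC and compared with a Bayes
factor from bridge sampling, cross-checked against an independent adaptive
2-D quadrature oracle. Auxiliary regressions: a hierarchical logistic model
of the non-Utilitarian choice rate and a mixed-effects response-time model.

**Cursor level.** After affine remapping (start button → (0,0), option
targets → (±1,1)) and time normalization to 101 bins, a hierarchical
state-space model tracks, bin by bin, how strongly the standardized
between-option differences in minimum pay-off ($D^{\min}$) and Gini
($D^{\mathrm{var}}$) steer the cursor toward the non-Utilitarian side:

$$x_{t,i,j} = \mu_{t,i} + \beta^{\min}_{t,i} D^{\min}_j +
\beta^{\mathrm{var}}_{t,i} D^{\mathrm{var}}_j + \varepsilon,\quad
\varepsilon \sim N(0, 0.005),$$

with participant coefficients scattered around population series that
evolve as Gaussian random walks pinned to zero at $t=1$. The sampler is a
purpose-built blocked Gibbs scheme (conjugate coefficient draws, FFBS for
the random walks, slice updates for SD hyperparameters). Outputs are
pointwise and simultaneous 95% highest-density bands and the first bin at
which each coefficient credibly departs from zero.

**Synthetic experiments.** `sim_config()` / `simulate_experiment()`
generate complete experiments — choice sets with a controlled correlation
(0.49 ± 0.1) between the two difference predictors, choices from either
utility model, response times, and 60 Hz trajectories from exactly the
state-space process the fits assume — so every stage is validated by
parameter recovery.

## Worked example

```r
library(alloctrace)

cfg <- sim_config(n_participants = 12, n_problems = 24)
sim <- simulate_experiment(cfg, seed = 1)
round(feature_correlation(sim$features), 3)

fit <- fit_choice_model(sim$trials, sim$problems, "quasi_maximin",
                        mcmc = mcmc_control(chains = 2), seed = 2)
print(fit)

nz <- preprocess_trajectories(sim$trajectories, sim$trials, cfg$geometry)
ss <- fit_statespace(nz, sim$trials, sim$features,
                     statespace_spec(chains = 2, warmup = 400, iter = 400,
                                     seed = 3))
print(ss)
```

```
[1] 0.585
quasi_maximin choice model (hierarchical mode): 12 participants, 288 trials
  max R-hat 1.037 (converged)
  mean alpha = 0.904
trajectory state-space fit: 12 participants, 288 trials, coefficients beta_min, beta_var
  max R-hat 1.023 (converged)
  beta_min: departure from zero at t = 32
  beta_var: departure from zero at t = 59
```

Reading the output: the realized predictor correlation (0.585) sits in the
generator's target band around 0.49; the fitted population of maximin
weights recovers the generating agents (mean α 0.90 against a generating
population centered at 0.85) with all split-R̂ below 1.1; and the
state-space fit reports the first time bin at which each population
coefficient's 95% pointwise HDI excludes zero — the minimum-difference
coefficient departs at bin 32, the Gini coefficient only at bin 59,
mirroring the generating series (ramps starting at bins 29 and 50).

The numbered scripts under `analysis/` run the same chain at full scale
(36 participants × 48 problems) with intermediate CSV/JSON artifacts under
`results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_preprocess.R
Rscript analysis/03_choice_models.R 1
Rscript analysis/04_statespace.R 1
Rscript analysis/05_report.R 1
```

## Package layout

- `R/` — implementation: allocation summaries and features, synthetic
  generator, trajectory preprocessing, choice models, marginal
  likelihoods, the state-space sampler, pipeline orchestration.
- `analysis/` — numbered narrative drivers over the package functions.
- `tests/testthat/` — unit, property and study-scale acceptance tests.
- `vignettes/alloctrace-methods.Rmd` — the models, their assumptions,
  parameter meanings, numerical choices and limitations.
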