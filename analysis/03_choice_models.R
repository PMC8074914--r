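#!/usr/bin/env Rscript
# Stage 3: utility-model estimation and comparison.
#
# Fits the quasi-maximin (A) and mean-variance (B) utility models
# hierarchically, compares them by bridge-sampled Bayes factor (with an
# independent quadrature cross-check), and runs the two auxiliary
# regressions: the hierarchical logistic model of the non-Utilitarian
# choice rate and the mixed-effects response-time model.

suppressMessages(library(alloctrace))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dat <- "results/data"
out <- "results"
trials <- read.csv(file.path(dat, "trials.csv"))
problems <- problems_from_table(file.path(dat, "problems.csv"))

mc <- mcmc_control() # choice models (package sampler)
mc_glmm <- mcmc_control(chains = 3, adapt = 800, burn = 800, iter = 1200)
fit_a <- fit_choice_model(trials, problems, "quasi_maximin", mcmc = mc,
                          seed = seed + 4L)
fit_b <- fit_choice_model(trials, problems, "mean_variance", mcmc = mc,
                          seed = seed + 5L)
message(sprintf("model A converged: %s (max R-hat %.3f); mean alpha %.2f",
                fit_a$converged, max(fit_a$rhat, na.rm = TRUE),
                mean(fit_a$participants$mean)))
message(sprintf("model B converged: %s (max R-hat %.3f); mean beta %.2f",
                fit_b$converged, max(fit_b$rhat, na.rm = TRUE),
                mean(fit_b$participants$mean)))

ml_a <- marginal_likelihood(fit_a, seed = seed + 6L)
ml_b <- marginal_likelihood(fit_b, seed = seed + 7L)
cmp <- compare_models(ml_a, ml_b)
print(cmp)

# independent-participant quadrature cross-check of the Bayes factor
by_part <- split(trials, trials$participant_id)
lml <- function(model) {
  sum(vapply(by_part, quadrature_oracle_logml, numeric(1),
             problems = problems, model = model, n_nodes = 60))
}
log_bf_quad <- lml("quasi_maximin") - lml("mean_variance")
message(sprintf("quadrature (independent-mode) log BF_AB = %.2f", log_bf_quad))

ab <- merge(fit_a$participants[, c("participant_id", "mean", "lower", "upper")],
            fit_b$participants[, c("participant_id", "mean", "lower", "upper")],
            by = "participant_id", suffixes = c("_alpha", "_beta"))
write.csv(ab, file.path(out, "alpha_beta.csv"), row.names = FALSE)
message(sprintf("correlation of participant alpha and beta: r = %.2f",
                cor(ab$mean_alpha, ab$mean_beta)))

rate <- fit_choice_rate(trials, mcmc = mc_glmm, seed = seed + 2L)
message(sprintf("choice-rate intercept (log-odds of N): %.2f [%.2f, %.2f]",
                rate$intercept, rate$ci[1], rate$ci[2]))
rt <- fit_rt_model(trials, mcmc = mc_glmm, seed = seed + 3L)
message(sprintf("rt effect of non-Utilitarian choice: %.3f s [%.3f, %.3f]",
                rt$effect, rt$ci[1], rt$ci[2]))

jsonlite::write_json(
  list(logml_A = cmp$logml_A, logml_B = cmp$logml_B,
       log_bf_AB = cmp$log_bf_AB, bf_AB = cmp$bf_AB, mcse = cmp$mcse,
       log_bf_AB_quadrature = log_bf_quad,
       alpha_beta_correlation = cor(ab$mean_alpha, ab$mean_beta),
       choice_rate_intercept = rate$intercept,
       choice_rate_ci = rate$ci,
       rt_effect = rt$effect, rt_ci = rt$ci),
  file.path(out, "choice_models.json"), auto_unbox = TRUE, digits = NA
)
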