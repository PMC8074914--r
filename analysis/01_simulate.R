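#!/usr/bin/env Rscript
# Stage 1: generate the synthetic experiment.
#
# 36 participants x 48 choice problems. Each problem pairs a Utilitarian
# option (larger total) with a non-Utilitarian option (larger minimum,
# smaller Gini); the realized correlation between the |minimum| and |Gini|
# difference predictors is constrained to 0.49 +/- 0.1. Quasi-maximin
# agents (population alpha 0.85 +/- 0.1) produce choices via a logistic
# rule, and 60 Hz cursor trajectories follow the state-space process the
# later stages fit.

suppressMessages(library(alloctrace))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config()
sim <- simulate_experiment(cfg, seed = seed)

write.csv(problems_table(sim$problems), file.path(out, "problems.csv"),
          row.names = FALSE)
write.csv(sim$features, file.path(out, "features.csv"), row.names = FALSE)
write.csv(sim$trials, file.path(out, "trials.csv"), row.names = FALSE)
write.csv(sim$trajectories, file.path(out, "trajectories.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(seed = seed, agents = sim$truth$agents,
       feature_correlation = sim$truth$feature_correlation,
       beta_min_series = cfg$beta_min_series,
       beta_var_series = cfg$beta_var_series),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA
)

message(sprintf("simulated %d trials from %d participants x %d problems",
                nrow(sim$trials), cfg$n_participants, cfg$n_problems))
message(sprintf("realized feature correlation r = %.3f (target 0.49)",
                sim$truth$feature_correlation))
message(sprintf("non-Utilitarian choices: %.1f%%; mean rt %.2f s",
                100 * mean(sim$trials$choice == "N"), mean(sim$trials$rt)))
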