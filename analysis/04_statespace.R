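#!/usr/bin/env Rscript
# Stage 4: trajectory state-space model.
#
# Fits the hierarchical random-walk-coefficient model to the normalized
# trajectories of the main experiment: per time bin, how strongly do the
# standardized |minimum| and |Gini| differences steer the cursor toward the
# non-Utilitarian option? Reports pointwise and simultaneous 95% HDIs and
# the first bin at which each population coefficient departs from zero.

suppressMessages(library(alloctrace))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
dat <- "results/data"
out <- "results"
trials <- read.csv(file.path(dat, "trials.csv"))
features <- read.csv(file.path(dat, "features.csv"))
features$problem_id <- as.character(features$problem_id)
trials$problem_id <- as.character(trials$problem_id)
normalized <- read.csv(file.path(out, "normalized.csv"))

fit <- fit_statespace(normalized, trials, features,
                      statespace_spec(seed = seed + 11L))
print(fit)
write.csv(coefficients_table(fit), file.path(out, "coefficients.csv"),
          row.names = FALSE)
dep <- departure_times(fit)
jsonlite::write_json(
  list(departure = as.list(dep$departure),
       min_exceeds_var_bins = which(dep$min_exceeds_var),
       max_rhat = max(fit$rhat, na.rm = TRUE),
       converged = fit$converged),
  file.path(out, "departures.json"), auto_unbox = TRUE, digits = NA
)
message(sprintf("minimum coefficient credibly exceeds the Gini coefficient at %d of 101 bins",
                sum(dep$min_exceeds_var)))
message(sprintf("posterior SD hyperparameters: %s",
                paste(sprintf("%s=%.4f", colnames(fit$sd_draws),
                              colMeans(fit$sd_draws)), collapse = ", ")))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE)
  ggplot2::ggsave("results/figures/coefficient_series.png",
                  plot_coefficients(fit), width = 7, height = 4, dpi = 150)
  message("wrote results/figures/coefficient_series.png")
}
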