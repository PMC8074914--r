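#!/usr/bin/env Rscript
# Stage 2: trajectory preprocessing.
#
# Maps raw pixel paths into the analysis frame (start button -> (0,0),
# left/right targets -> (-1,1)/(1,1)), orients x toward the non-Utilitarian
# option, and time-normalizes every trial to 101 equal bins. All trials are
# retained. Also writes the per-choice mean trajectories.

suppressMessages(library(alloctrace))
dat <- "results/data"
out <- "results"
trials <- read.csv(file.path(dat, "trials.csv"))
trajectories <- read.csv(file.path(dat, "trajectories.csv"))

normalized <- preprocess_trajectories(trajectories, trials, make_geometry())
write.csv(normalized, file.path(out, "normalized.csv"), row.names = FALSE)
mt <- mean_trajectories(normalized)
write.csv(mt, file.path(out, "mean_trajectories.csv"), row.names = FALSE)

stopifnot(all(table(paste(normalized$participant_id,
                          normalized$trial_index)) == 101))
message(sprintf("normalized %d trajectories to 101 bins each",
                nrow(normalized) / 101))
for (ch in unique(mt$choice)) {
  end_x <- mt$mean_x[mt$choice == ch & mt$bin == 101]
  message(sprintf("  %s-choice mean path: x at t=101 is %+.2f (n = %d)",
                  ch, end_x, mt$n[mt$choice == ch][1]))
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE)
  ggplot2::ggsave("results/figures/mean_trajectories.png",
                  plot_mean_trajectories(mt), width = 6, height = 4, dpi = 150)
  message("wrote results/figures/mean_trajectories.png")
}
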