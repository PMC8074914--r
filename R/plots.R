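#' Plot mean cursor trajectories by choice
#'
#' Per-bin mean oriented x position with a standard-error ribbon,
#' separately for Utilitarian and non-Utilitarian choices.
#'
#' @param mean_traj output of [mean_trajectories()].
#' @return a ggplot object.
#' @export
plot_mean_trajectories <- function(mean_traj) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  lab <- c(N = "non-Utilitarian", U = "Utilitarian")
  mean_traj$option <- lab[mean_traj$choice]
  ggplot2::ggplot(mean_traj, ggplot2::aes(
    x = bin, y = mean_x,
    colour = option, fill = option
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = mean_x - sem_x,
      ymax = mean_x + sem_x
    ), alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "normalized time bin", y = "x position (+1 = non-Utilitarian side)",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot population coefficient series with credible bands
#'
#' Posterior mean of each population coefficient series over the 101 time
#' bins, with the 95% pointwise HDI as a ribbon and the 95% simultaneous
#' band as dotted lines.
#'
#' @param fit a `statespace_fit`.
#' @return a ggplot object.
#' @export
plot_coefficients <- function(fit) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
  tab <- coefficients_table(fit)
  lab <- c(beta_min = "minimum", beta_var = "Gini (variance)",
           beta_total = "total")
  tab$predictor <- lab[tab$coefficient]
  ggplot2::ggplot(tab, ggplot2::aes(
    x = t, y = mean,
    colour = predictor, fill = predictor
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = hdi_low, ymax = hdi_high
    ), alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = simult_low), linetype = 3) +
    ggplot2::geom_line(ggplot2::aes(y = simult_high), linetype = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(
      x = "normalized time bin", y = "population coefficient",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("bin", "mean_x", "sem_x", "option", "t",
                         "hdi_low", "hdi_high", "simult_low", "simult_high",
                         "predictor"))
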