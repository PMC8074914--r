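#' Quasi-maximin utility
#'
#' `U(x) = alpha * min(payoffs) + (1 - alpha) * total(payoffs)`: a trade-off
#' between the worst-off recipient's pay-off and overall efficiency.
#' `alpha` in `[0, 1]` indexes concern for the minimum.
#'
#' @param payoffs numeric vector of three pay-offs (yen).
#' @param alpha maximin weight in `[0, 1]`.
#' @return utility on the yen scale.
#' @export
utility_quasi_maximin <- function(payoffs, alpha) {
  check_allocation(payoffs)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  alpha * min(payoffs) + (1 - alpha) * sum(payoffs)
}

#' Mean-variance utility
#'
#' `U(x) = mean(payoffs) - beta * variance(payoffs)`: a trade-off between
#' average pay-off and dispersion. `beta` is unconstrained; larger values
#' express stronger egalitarian (variance) concern. The variance is the
#' population variance (divisor `n = 3`) by default.
#'
#' @param payoffs numeric vector of three pay-offs (yen).
#' @param beta egalitarian weight (any real number).
#' @param divisor variance divisor convention, see [payoff_variance()].
#' @return utility on the yen scale.
#' @export
utility_mean_variance <- function(payoffs, beta, divisor = c("population", "sample")) {
  check_allocation(payoffs)
  if (any(!is.finite(beta))) stop("beta must be finite")
  mean(payoffs) - beta * payoff_variance(payoffs, divisor = divisor)
}

# Per-problem utility-difference ingredients U(N) - U(U), on a rescaled unit
# (yen / scale) so the inverse temperature is order one. For the
# quasi-maximin model the difference is linear in alpha:
#   dU(alpha) = alpha * a + (1 - alpha) * b,  a = dmin, b = dtotal (scaled);
# for the mean-variance model it is linear in beta:
#   dU(beta) = dmean - beta * dvariance (variance scaled by scale^2).
problem_predictors <- function(problems, scale = 100) {
  do.call(rbind, lapply(problems, function(p) {
    data.frame(
      problem_id = p$problem_id,
      a_min = (p$summary_n$min - p$summary_u$min) / scale,
      b_tot = (p$summary_n$total - p$summary_u$total) / scale,
      d_mean = (p$summary_n$mean - p$summary_u$mean) / scale,
      d_var = (p$summary_n$variance - p$summary_u$variance) / scale^2,
      stringsAsFactors = FALSE
    )
  }))
}

# utility difference U(N) - U(U) per (participant parameter, problem) pair;
# theta is alpha (model A) or beta (model B); returns length(theta) x nrow(pred)
utility_diff_matrix <- function(pred, theta, model = c("quasi_maximin", "mean_variance")) {
  model <- match.arg(model)
  if (model == "quasi_maximin") {
    outer(theta, pred$a_min) + outer(1 - theta, pred$b_tot)
  } else {
    matrix(pred$d_mean, length(theta), nrow(pred), byrow = TRUE) -
      outer(theta, pred$d_var)
  }
}
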