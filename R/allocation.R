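#' Validate a three-recipient allocation
#'
#' Allocations in this package are vectors of three non-negative pay-offs
#' (in yen) for the three recipients of a choice option. The task is fixed
#' at three recipients, so the length is checked strictly.
#'
#' @param payoffs numeric vector of three non-negative pay-offs.
#' @return the pay-offs, invisibly, after validation.
#' @keywords internal
check_allocation <- function(payoffs) {
  if (!is.numeric(payoffs) || length(payoffs) != 3L) {
    stop("an allocation must be a numeric vector of exactly three pay-offs")
  }
  if (anyNA(payoffs) || any(payoffs < 0)) {
    stop("pay-offs must be non-negative and non-missing")
  }
  invisible(payoffs)
}

#' Gini coefficient of a three-recipient allocation
#'
#' Relative mean absolute difference: `G = sum_ij |p_i - p_j| / (2 n^2 mu)`
#' with `n = 3` and `mu` the mean pay-off. Ranges from 0 (perfect equality)
#' to `(n - 1)/n = 2/3` for three recipients; no small-sample correction is
#' applied, matching the standard economics definition shown to participants.
#'
#' @param payoffs numeric vector of three non-negative pay-offs (yen).
#' @return Gini coefficient in `[0, 2/3]`.
#' @examples
#' gini(c(500, 500, 500)) # 0
#' gini(c(0, 0, 900))     # 2/3
#' @export
gini <- function(payoffs) {
  check_allocation(payoffs)
  mu <- mean(payoffs)
  if (mu <= 0) stop("Gini coefficient is undefined for an all-zero allocation")
  sum(abs(outer(payoffs, payoffs, "-"))) / (2 * 9 * mu)
}

#' Population variance of a three-recipient allocation
#'
#' Variance with divisor `n = 3` (the mean-variance convention in finance),
#' in squared yen. Set `divisor = "sample"` for the `n - 1` version.
#'
#' @param payoffs numeric vector of three non-negative pay-offs (yen).
#' @param divisor `"population"` (default, divisor `n`) or `"sample"`
#'   (divisor `n - 1`).
#' @return variance in yen squared.
#' @examples
#' payoff_variance(c(100, 200, 300)) # 6666.67
#' @export
payoff_variance <- function(payoffs, divisor = c("population", "sample")) {
  check_allocation(payoffs)
  divisor <- match.arg(divisor)
  d <- if (divisor == "population") 3 else 2
  sum((payoffs - mean(payoffs))^2) / d
}

#' Summaries of one allocation option
#'
#' @param payoffs numeric vector of three non-negative pay-offs (yen).
#' @return named list with the sorted pay-offs (`min`, `med`, `high`),
#'   `total`, `mean`, `gini` and population `variance`.
#' @export
allocation_summary <- function(payoffs) {
  check_allocation(payoffs)
  s <- sort(payoffs)
  list(
    min = s[1], med = s[2], high = s[3],
    total = sum(payoffs), mean = mean(payoffs),
    gini = gini(payoffs), variance = payoff_variance(payoffs)
  )
}
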