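#' Highest-density interval of a sample
#'
#' Narrowest interval containing `mass` of the draws (shortest window over
#' the sorted sample). For symmetric unimodal posteriors this is close to
#' the equal-tailed interval; for skewed or boundary-piled posteriors it is
#' shorter and shifted toward the mode.
#'
#' @param draws numeric vector of posterior draws.
#' @param mass probability mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hdi_interval <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass <= 1)
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n == 0) stop("no finite draws")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  j <- which.min(widths)
  c(x[j], x[j + k])
}

#' Pointwise HDIs over time bins
#'
#' @param draws matrix of posterior draws (rows = draws, columns = time
#'   bins) of a coefficient series.
#' @param mass probability mass (default 0.95).
#' @return data.frame with `t`, `mean`, `lower`, `upper`.
#' @export
pointwise_hdi <- function(draws, mass = 0.95) {
  draws <- as.matrix(draws)
  iv <- apply(draws, 2, hdi_interval, mass = mass)
  data.frame(
    t = seq_len(ncol(draws)), mean = colMeans(draws),
    lower = iv[1, ], upper = iv[2, ]
  )
}

#' Simultaneous credible band over time bins
#'
#' Band with joint coverage `mass` over all bins: the per-bin posterior SD
#' is scaled by the `mass` quantile of each draw's maximum standardized
#' absolute deviation from the posterior mean across bins. Degenerate bins
#' (zero SD, e.g. a coefficient pinned to zero at t = 1) are excluded from
#' the maximum and get a zero-width band.
#'
#' @param draws matrix of joint posterior draws (rows = draws, columns =
#'   time bins).
#' @param mass joint probability mass (default 0.95).
#' @return data.frame with `t`, `mean`, `lower`, `upper`.
#' @export
simultaneous_band <- function(draws, mass = 0.95) {
  draws <- as.matrix(draws)
  m <- colMeans(draws)
  s <- apply(draws, 2, stats::sd)
  live <- s > 0
  if (!any(live)) {
    return(data.frame(t = seq_along(m), mean = m, lower = m, upper = m))
  }
  z <- abs(sweep(sweep(draws[, live, drop = FALSE], 2, m[live]), 2, s[live], "/"))
  k <- stats::quantile(apply(z, 1, max), mass, names = FALSE)
  data.frame(t = seq_along(m), mean = m, lower = m - k * s, upper = m + k * s)
}

#' First departure of a coefficient series from zero
#'
#' Scans the pointwise HDIs of each population coefficient series and
#' reports the first time bin whose interval excludes zero, the per-bin
#' sign of credible departures, and the bins at which the minimum
#' coefficient credibly exceeds the Gini (variance) coefficient (the HDI of
#' the per-draw difference excludes zero).
#'
#' @param fit a `statespace_fit` (or any list with element `pop_draws`, a
#'   named list of draws matrices with columns = 101 bins).
#' @param mass probability mass for the pointwise HDIs.
#' @return list with per-coefficient `departure` (first bin in 2..101, or
#'   `NA` if none), `sign` (per-bin -1/0/+1 of credible departures), and
#'   `min_exceeds_var` (logical per bin), plus the HDIs used.
#' @export
departure_times <- function(fit, mass = 0.95) {
  draws <- fit$pop_draws
  stopifnot(is.list(draws), length(draws) >= 1)
  per_coef <- lapply(draws, function(d) {
    h <- pointwise_hdi(d, mass)
    excl <- h$lower > 0 | h$upper < 0
    excl[1] <- FALSE # bin 1 is pinned to zero by construction
    list(
      hdi = h,
      departure = if (any(excl)) min(which(excl)) else NA_integer_,
      sign = ifelse(excl, sign(h$lower + h$upper), 0L)
    )
  })
  out <- list(
    departure = vapply(per_coef, function(p) p$departure, integer(1)),
    sign = lapply(per_coef, function(p) p$sign),
    hdi = lapply(per_coef, function(p) p$hdi)
  )
  if (all(c("beta_min", "beta_var") %in% names(draws))) {
    dd <- draws$beta_min - draws$beta_var
    h <- pointwise_hdi(dd, mass)
    out$min_exceeds_var <- h$lower > 0
  }
  out
}

#' Split-chain Gelman-Rubin statistic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain drift also registers as non-convergence. Values below
#' 1.1 are taken as converged throughout the package.
#'
#' @param chains list of draws matrices (iterations x parameters), one per
#'   chain, with identical column names.
#' @return named vector of R-hat values (NA for constant parameters).
#' @export
split_rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1)
  halves <- list()
  for (ch in chains) {
    ch <- as.matrix(ch)
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[seq_len(h), , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  mns <- sapply(halves, colMeans)
  vrs <- sapply(halves, function(h) apply(h, 2, stats::var))
  if (is.null(dim(mns))) {
    mns <- matrix(mns, nrow = 1)
    vrs <- matrix(vrs, nrow = 1)
  }
  n <- nrow(halves[[1]])
  w <- rowMeans(vrs)
  b <- n * apply(mns, 1, stats::var)
  rhat <- sqrt(((n - 1) / n * w + b / n) / w)
  names(rhat) <- colnames(as.matrix(chains[[1]]))
  rhat
}
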