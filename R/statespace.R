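#' Settings for the trajectory state-space model
#'
#' The model regresses the cursor's oriented x position at every normalized
#' time bin on the standardized minimum and Gini difference predictors,
#' with participant-level coefficients drawn around population coefficient
#' series that evolve as Gaussian random walks pinned to zero at t = 1.
#' All `N(mean, scale)` noise terms are parameterized by their standard
#' deviation; in particular the observation noise SD defaults to 0.005.
#'
#' @param obs_noise_sd fixed observation noise SD (normalized x units).
#' @param include_total if TRUE, adds the standardized total-difference
#'   predictor as a third coefficient series.
#' @param mu_dynamics `"linear_drift"` (per-participant constant drift, the
#'   literal reading of the intercept recursion) or `"random_walk"`
#'   (time-indexed intercept innovations with participant-specific SD).
#' @param eta_mode `"shared"` (one participant-deviation SD per
#'   coefficient; default) or `"per_time"` (an SD per time bin, weakly
#'   identified and slower).
#' @param prior_sd_scale half-normal prior scale for all SD
#'   hyperparameters (features are standardized, so unit scale is weak).
#' @param chains,warmup,iter MCMC geometry (at least 2 chains so R-hat is
#'   defined).
#' @param seed integer seed.
#' @return list of class `statespace_spec`.
#' @export
statespace_spec <- function(obs_noise_sd = 0.005,
                            include_total = FALSE,
                            mu_dynamics = c("linear_drift", "random_walk"),
                            eta_mode = c("shared", "per_time"),
                            prior_sd_scale = 1,
                            chains = 3, warmup = 800, iter = 600,
                            seed = 1) {
  mu_dynamics <- match.arg(mu_dynamics)
  eta_mode <- match.arg(eta_mode)
  stopifnot(obs_noise_sd > 0, prior_sd_scale > 0, chains >= 2,
            warmup >= 50, iter >= 100, iter %% 2 == 0)
  structure(as.list(environment()), class = "statespace_spec")
}

# univariate slice sampler (Neal 2003, stepping out and shrinkage)
slice_1d <- function(x0, logf, w = 0.5, max_steps = 30) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at a zero-density point")
  y <- f0 + log(stats::runif(1))
  l <- x0 - stats::runif(1) * w
  r <- l + w
  i <- 0
  while (logf(l) > y && i < max_steps) { l <- l - w; i <- i + 1 }
  i <- 0
  while (logf(r) > y && i < max_steps) { r <- r + w; i <- i + 1 }
  repeat {
    x1 <- stats::runif(1, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# slice update of an SD with half-normal prior, given n normal deviations
# with sum of squares ss; operates on log(sigma)
update_sd <- function(sigma, n, ss, prior_scale) {
  logf <- function(ls) {
    s <- exp(ls)
    (1 - n) * ls - ss / (2 * s^2) - s^2 / (2 * prior_scale^2)
  }
  exp(slice_1d(log(sigma), logf))
}

# forward-filter backward-sample random walks pinned to 0 at t = 1,
# vectorized over series (columns): obs[t, s] with observation variance
# v (vector over series, or nt x ns matrix for time-varying noise) and
# innovation variance q (vector over series); obs at t = 1 is ignored.
ffbs_rw <- function(obs, v, q) {
  nt <- nrow(obs)
  ns <- ncol(obs)
  if (is.null(dim(v))) v <- matrix(v, nt, ns, byrow = TRUE)
  m <- matrix(0, nt, ns)
  cc <- matrix(0, nt, ns)
  for (t in 2:nt) {
    r <- cc[t - 1, ] + q
    k <- r / (r + v[t, ])
    m[t, ] <- m[t - 1, ] + k * (obs[t, ] - m[t - 1, ])
    cc[t, ] <- (1 - k) * r
  }
  out <- matrix(0, nt, ns)
  out[nt, ] <- stats::rnorm(ns, m[nt, ], sqrt(cc[nt, ]))
  if (nt == 2) return(out)
  for (t in (nt - 1):2) {
    g <- cc[t, ] / (cc[t, ] + q)
    mean_t <- m[t, ] + g * (out[t + 1, ] - m[t, ])
    var_t <- (1 - g) * cc[t, ]
    out[t, ] <- stats::rnorm(ns, mean_t, sqrt(var_t))
  }
  out
}

# assemble per-participant sufficient statistics from the long tables
statespace_data <- function(normalized, trials, features, spec) {
  need <- c("participant_id", "trial_index", "bin", "x")
  stopifnot(all(need %in% names(normalized)))
  zcols <- c("z_diff_min", "z_diff_var")
  if (spec$include_total) zcols <- c(zcols, "z_diff_total")
  for (zc in zcols) {
    z <- features[[zc]]
    if (abs(mean(z)) > 1e-6 || abs(mean((z - mean(z))^2) - 1) > 1e-6) {
      stop("features must be standardized (mean 0, variance 1): ", zc,
           " is not; run compute_features() on the problem set")
    }
  }
  key <- paste(normalized$participant_id, normalized$trial_index)
  cnt <- table(key)
  if (any(cnt != 101)) {
    stop("every trajectory must have exactly 101 bins; found counts ",
         paste(unique(cnt[cnt != 101]), collapse = ", "))
  }
  tkey <- paste(trials$participant_id, trials$trial_index)
  if (!all(unique(key) %in% tkey)) stop("trajectory without a matching trial")
  prow <- match(trials$problem_id, features$problem_id)
  if (anyNA(prow)) stop("every trial must match a problem in the feature table")
  ord <- order(normalized$participant_id, normalized$trial_index, normalized$bin)
  nz <- normalized[ord, ]
  pids <- unique(nz$participant_id)
  dat <- lapply(pids, function(p) {
    sub <- nz[nz$participant_id == p, ]
    tix <- unique(sub$trial_index)
    xmat <- matrix(sub$x, nrow = 101) # bins x trials
    rows <- match(paste(p, tix), tkey)
    z <- as.matrix(features[prow[rows], zcols, drop = FALSE])
    list(
      x = xmat, z = z, j = length(tix),
      ztz = crossprod(z), czs = colSums(z),
      ztx = t(xmat %*% z), # K x 101
      sx = rowSums(xmat)
    )
  })
  list(participants = dat, pids = pids, k = length(zcols), zcols = zcols)
}

#' Fit the hierarchical trajectory state-space model
#'
#' The observation model at time bin t (2..101), participant i, trial j is
#' `x = mu[t,i] + bMin[t,i] * z_diff_min[j] + bVar[t,i] * z_diff_var[j]
#' (+ bTot[t,i] * z_diff_total[j]) + e`, with `e ~ N(0, obs_noise_sd)`.
#' Participant coefficients scatter normally around population series that
#' evolve as Gaussian random walks from zero at t = 1; the participant
#' intercept follows a constant per-participant drift (or a random walk,
#' see [statespace_spec()]). Everything is linear-Gaussian given the SD
#' hyperparameters, so sampling uses a blocked Gibbs scheme: conjugate
#' draws for participant coefficients and drifts, forward-filtering
#' backward-sampling for the population series (and random-walk
#' intercepts), and slice updates for the half-normal SD hyperparameters.
#' Split R-hat is computed for every parameter (population series via full
#' draws; participant coefficients via per-half-chain moments) and the fit
#' is flagged non-converged if any reaches 1.1.
#'
#' @param normalized output of [preprocess_trajectories()] (101 bins).
#' @param trials trial table linking trials to problems.
#' @param features [compute_features()] output (standardized columns are
#'   required and checked).
#' @param spec a [statespace_spec()].
#' @return object of class `statespace_fit`: `pop_draws` (named list of
#'   draws x 101 matrices for `beta_min`, `beta_var`, optionally
#'   `beta_total`), `sd_draws`, `delta_draws` (or `mu_last` summaries),
#'   `participant_mean`/`participant_sd` arrays, `pointwise` and
#'   `simultaneous` 95% bands, `rhat`, `converged`, and bookkeeping.
#' @export
fit_statespace <- function(normalized, trials, features, spec = statespace_spec()) {
  sd0 <- statespace_data(normalized, trials, features, spec)
  dat <- sd0$participants
  np <- length(dat)
  k <- sd0$k
  nb <- 101L
  s2e <- spec$obs_noise_sd^2
  n_draw <- spec$iter
  coef_names <- c("beta_min", "beta_var", if (spec$include_total) "beta_total")
  per_time <- spec$eta_mode == "per_time"
  rw_mu <- spec$mu_dynamics == "random_walk"
  wsum2 <- sum((1:100)^2)

  chains_pop <- vector("list", spec$chains)
  chains_sd <- vector("list", spec$chains)
  chains_drift <- vector("list", spec$chains)
  half_stats <- list() # per half-chain moments of participant coefficients
  part_sum <- array(0, c(nb, k, np))
  part_sum2 <- array(0, c(nb, k, np))

  for (ch in seq_len(spec$chains)) {
    set.seed((abs(spec$seed) * 131L + ch * 7919L) %% 2147483646L + 1L)
    beta <- array(0, c(nb, k, np))
    bpop <- matrix(0, nb, k)
    sig_eta <- if (per_time) {
      matrix(exp(stats::runif(100 * k, log(0.02), log(0.5))), 100, k)
    } else {
      exp(stats::runif(k, log(0.02), log(0.5)))
    }
    sig_zeta <- exp(stats::runif(k, log(0.005), log(0.1)))
    if (rw_mu) {
      mu <- matrix(0, nb, np)
      sig_del <- exp(stats::runif(np, log(0.002), log(0.05)))
    } else {
      delta <- stats::rnorm(np, 0, 0.002)
      sig_del <- exp(stats::runif(1, log(0.002), log(0.05)))
    }
    pop_store <- matrix(NA_real_, n_draw, nb * k)
    sd_store <- matrix(NA_real_, n_draw, 2 * k + 1)
    drift_store <- matrix(NA_real_, n_draw, np)
    h_n <- c(0, 0)
    h_sum <- list(array(0, c(nb, k, np)), array(0, c(nb, k, np)))
    h_sum2 <- list(array(0, c(nb, k, np)), array(0, c(nb, k, np)))

    for (it in seq_len(spec$warmup + n_draw)) {
      # participant coefficients | population series, drifts, SDs
      for (i in seq_len(np)) {
        d <- dat[[i]]
        mu_i <- if (rw_mu) mu[, i] else (0:100) * delta[i]
        if (!per_time) {
          pr <- 1 / sig_eta^2
          q <- d$ztz / s2e + diag(pr, k)
          r <- chol(q)
          rhs <- (d$ztx[, 2:nb, drop = FALSE] -
                    outer(d$czs, mu_i[2:nb])) / s2e +
            t(bpop[2:nb, , drop = FALSE]) * pr
          mm <- backsolve(r, backsolve(r, rhs, transpose = TRUE))
          beta[2:nb, , i] <- t(mm + backsolve(r, matrix(stats::rnorm(k * (nb - 1)), k)))
        } else {
          for (t in 2:nb) {
            pr <- 1 / sig_eta[t - 1, ]^2
            q <- d$ztz / s2e + diag(pr, k)
            r <- chol(q)
            rhs <- (d$ztx[, t] - d$czs * mu_i[t]) / s2e + bpop[t, ] * pr
            mm <- backsolve(r, backsolve(r, rhs, transpose = TRUE))
            beta[t, , i] <- mm + backsolve(r, stats::rnorm(k))
          }
        }
      }

      # intercept drift | coefficients
      resid_sums <- sapply(seq_len(np), function(i) {
        d <- dat[[i]]
        d$sx[2:nb] - as.vector(beta[2:nb, , i] %*% d$czs)
      }) # (nb-1) x np: per-bin sums over trials of x - z * beta
      if (!rw_mu) {
        for (i in seq_len(np)) {
          prec <- wsum2 * dat[[i]]$j / s2e + 1 / sig_del^2
          mn <- sum((1:100) * resid_sums[, i]) / s2e / prec
          delta[i] <- stats::rnorm(1, mn, 1 / sqrt(prec))
        }
        sig_del <- update_sd(sig_del, np, sum(delta^2), spec$prior_sd_scale)
      } else {
        jn <- vapply(dat, `[[`, numeric(1), "j")
        obs <- rbind(0, sweep(resid_sums, 2, jn, "/"))
        mu <- ffbs_rw(obs, s2e / jn, sig_del^2)
        for (i in seq_len(np)) {
          inn <- diff(mu[, i])
          sig_del[i] <- update_sd(sig_del[i], length(inn), sum(inn^2),
                                  spec$prior_sd_scale)
        }
      }

      # population series | participant coefficients (FFBS per coefficient)
      bbar <- apply(beta, c(1, 2), mean)
      for (kk in seq_len(k)) {
        v <- if (per_time) {
          matrix(c(1, sig_eta[, kk]^2 / np), ncol = 1) # row 1 unused
        } else {
          sig_eta[kk]^2 / np
        }
        bpop[, kk] <- ffbs_rw(matrix(bbar[, kk], ncol = 1),
                              v = v, q = sig_zeta[kk]^2)
      }

      # SD hyperparameters
      for (kk in seq_len(k)) {
        inn <- diff(bpop[, kk])
        sig_zeta[kk] <- update_sd(sig_zeta[kk], length(inn), sum(inn^2),
                                  spec$prior_sd_scale)
        # interweaved ancillary move: rescale the whole population series
        # with its innovation SD (holding standardized innovations fixed),
        # so sigma_zeta can travel when the series is far from zero
        ls_p <- log(sig_zeta[kk]) + stats::rnorm(1) * 0.3
        ratio <- exp(ls_p) / sig_zeta[kk]
        b_p <- bpop[, kk] * ratio
        ev <- if (per_time) sig_eta[, kk]^2 else rep(sig_eta[kk]^2, nb - 1)
        dev_cur <- bbar[2:nb, kk] - bpop[2:nb, kk]
        dev_p <- bbar[2:nb, kk] - b_p[2:nb]
        log_r <- sum((dev_cur^2 - dev_p^2) * np / (2 * ev)) +
          log_halfnormal(exp(ls_p), spec$prior_sd_scale) + ls_p -
          log_halfnormal(sig_zeta[kk], spec$prior_sd_scale) - log(sig_zeta[kk])
        if (log(stats::runif(1)) < log_r) {
          sig_zeta[kk] <- exp(ls_p)
          bpop[, kk] <- b_p
        }
        dev <- beta[2:nb, kk, ] - bpop[2:nb, kk] # 100 x np, recycled by column
        if (!per_time) {
          sig_eta[kk] <- update_sd(sig_eta[kk], length(dev), sum(dev^2),
                                   spec$prior_sd_scale)
        } else {
          for (t in 1:100) {
            sig_eta[t, kk] <- update_sd(sig_eta[t, kk], np, sum(dev[t, ]^2),
                                        spec$prior_sd_scale)
          }
        }
      }

      if (it > spec$warmup) {
        j <- it - spec$warmup
        pop_store[j, ] <- as.vector(bpop)
        sd_store[j, ] <- c(sig_zeta, if (per_time) colMeans(sig_eta) else sig_eta,
                           mean(sig_del))
        drift_store[j, ] <- if (rw_mu) mu[nb, ] else delta
        half <- if (j <= n_draw / 2) 1L else 2L
        h_n[half] <- h_n[half] + 1
        h_sum[[half]] <- h_sum[[half]] + beta
        h_sum2[[half]] <- h_sum2[[half]] + beta^2
        part_sum <- part_sum + beta
        part_sum2 <- part_sum2 + beta^2
      }
    }
    colnames(pop_store) <- paste0(rep(coef_names, each = nb), "[",
                                  rep(seq_len(nb), k), "]")
    colnames(sd_store) <- c(paste0("sigma_zeta_", sub("beta_", "", coef_names)),
                            paste0("sigma_eta_", sub("beta_", "", coef_names)),
                            "sigma_delta")
    chains_pop[[ch]] <- pop_store
    chains_sd[[ch]] <- sd_store
    chains_drift[[ch]] <- drift_store
    half_stats[[length(half_stats) + 1]] <- list(n = h_n[1], s = h_sum[[1]], s2 = h_sum2[[1]])
    half_stats[[length(half_stats) + 1]] <- list(n = h_n[2], s = h_sum[[2]], s2 = h_sum2[[2]])
  }

  total <- spec$chains * n_draw
  pop_all <- do.call(rbind, chains_pop)
  pop_draws <- stats::setNames(lapply(seq_len(k), function(kk) {
    pop_all[, (kk - 1) * nb + seq_len(nb), drop = FALSE]
  }), coef_names)
  sd_all <- do.call(rbind, chains_sd)
  drift_all <- do.call(rbind, chains_drift)

  # R-hat: population series (excluding the pinned t = 1), SDs, drifts
  live <- as.vector(sapply(seq_len(k), function(kk) (kk - 1) * nb + 2:nb))
  rhat_pop <- split_rhat(lapply(chains_pop, function(m) m[, live, drop = FALSE]))
  rhat_sd <- split_rhat(chains_sd)
  rhat_drift <- split_rhat(lapply(chains_drift, function(m) {
    colnames(m) <- paste0("drift[", seq_len(np), "]")
    m
  }))
  # participant coefficients from per-half-chain moments
  hm <- sapply(half_stats, function(h) as.vector(h$s / h$n))
  hv <- sapply(half_stats, function(h) {
    as.vector((h$s2 - h$s^2 / h$n) / (h$n - 1))
  })
  nh <- half_stats[[1]]$n
  w <- rowMeans(hv)
  b <- nh * apply(hm, 1, stats::var)
  rhat_part <- sqrt(((nh - 1) / nh * w + b / nh) / w)
  rhat_part <- rhat_part[is.finite(rhat_part)] # t = 1 entries are constant zero
  rhat <- c(rhat_pop, rhat_sd, rhat_drift,
            stats::setNames(rhat_part, paste0("beta_part[", seq_along(rhat_part), "]")))

  pm <- part_sum / total
  pv <- (part_sum2 - part_sum^2 / total) / (total - 1)
  fit <- structure(
    list(
      pop_draws = pop_draws,
      sd_draws = sd_all,
      drift_draws = drift_all,
      participant_mean = pm,
      participant_sd = sqrt(pmax(pv, 0)),
      pointwise = lapply(pop_draws, pointwise_hdi),
      simultaneous = lapply(pop_draws, simultaneous_band),
      rhat = rhat,
      converged = all(is.na(rhat) | rhat < 1.1),
      coef_names = coef_names,
      participant_ids = sd0$pids,
      spec = spec,
      n_participants = np, n_trials = sum(vapply(dat, `[[`, numeric(1), "j"))
    ),
    class = "statespace_fit"
  )
  fit
}

#' @export
print.statespace_fit <- function(x, ...) {
  dep <- departure_times(x)
  cat(sprintf(
    "trajectory state-space fit: %d participants, %d trials, coefficients %s\n  max R-hat %.3f (%s)\n",
    x$n_participants, x$n_trials, paste(x$coef_names, collapse = ", "),
    max(x$rhat, na.rm = TRUE), if (x$converged) "converged" else "NOT CONVERGED"
  ))
  for (nm in x$coef_names) {
    cat(sprintf("  %s: departure from zero at t = %s\n", nm,
                ifelse(is.na(dep$departure[nm]), "none", dep$departure[nm])))
  }
  invisible(x)
}

#' Fit the state-space model with the total-difference covariate
#'
#' Convenience wrapper for the robustness analysis that statistically
#' controls for the total element: same model with the standardized
#' `diff_total` as a third coefficient series.
#'
#' @inheritParams fit_statespace
#' @return a `statespace_fit` with three population series.
#' @export
fit_statespace_with_total <- function(normalized, trials, features,
                                      spec = statespace_spec()) {
  spec$include_total <- TRUE
  fit_statespace(normalized, trials, features, spec)
}

#' Tabulate population coefficient series with credible bands
#'
#' @param fit a `statespace_fit`.
#' @return data.frame with `t`, `coefficient`, `mean`, `hdi_low`,
#'   `hdi_high`, `simult_low`, `simult_high`.
#' @export
coefficients_table <- function(fit) {
  do.call(rbind, lapply(fit$coef_names, function(nm) {
    pw <- fit$pointwise[[nm]]
    sb <- fit$simultaneous[[nm]]
    data.frame(
      t = pw$t, coefficient = nm, mean = pw$mean,
      hdi_low = pw$lower, hdi_high = pw$upper,
      simult_low = sb$lower, simult_high = sb$upper,
      stringsAsFactors = FALSE
    )
  }))
}
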