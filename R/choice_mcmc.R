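# MCMC engine for the choice models: adaptive Metropolis-within-Gibbs.
#
# Participant parameters are updated jointly per participant by a 2-D
# random-walk proposal on the unconstrained scale (logit alpha or raw
# beta, log tau), with the likelihood of all participants evaluated in one
# vectorized pass per sweep; population hyperparameters are updated given
# the participant draws by an exact conjugate draw (locations) and a slice
# step (half-normal scales). This keeps each sweep at O(trials) flops, so
# study-scale fits (36 x 48) run in seconds.

# per-participant Bernoulli log likelihood for parameter vectors theta, tau
choice_loglik_by_part <- function(dat, model, theta, tau) {
  if (model == "quasi_maximin") {
    du <- theta[dat$pid] * dat$a[dat$prob] + (1 - theta[dat$pid]) * dat$b[dat$prob]
  } else {
    du <- dat$dm[dat$prob] - theta[dat$pid] * dat$dv[dat$prob]
  }
  eta <- tau[dat$pid] * du
  ll <- numeric(dat$N)
  y1 <- dat$y == 1L
  ll[y1] <- stats::plogis(eta[y1], log.p = TRUE)
  ll[!y1] <- stats::plogis(-eta[!y1], log.p = TRUE)
  as.vector(rowsum(ll, dat$pid, reorder = TRUE))
}

run_choice_chain <- function(dat, model, mode, priors, mcmc, chain_seed) {
  set.seed(chain_seed)
  p <- dat$P
  hier <- mode == "hierarchical"
  logit_link <- model == "quasi_maximin"
  # unconstrained participant states: l_th (logit alpha or beta), l_t (log tau)
  l_th <- stats::rnorm(p, 0, 0.5) + if (logit_link) 1 else 0.3
  l_t <- stats::rnorm(p, 0, 0.5)
  if (hier) {
    if (logit_link) {
      h <- list(mu_mean = priors$mu_alpha_mean, mu_sd = priors$mu_alpha_sd,
                sig_scale = priors$sigma_alpha_scale)
    } else {
      h <- list(mu_mean = priors$mu_beta_mean, mu_sd = priors$mu_beta_sd,
                sig_scale = priors$sigma_beta_scale)
    }
    mu_th <- stats::rnorm(1, h$mu_mean, 0.5)
    sig_th <- exp(stats::runif(1, log(0.2), log(1)))
    mu_t <- stats::rnorm(1, priors$mu_logtau_mean, 0.5)
    sig_t <- exp(stats::runif(1, log(0.2), log(1)))
  }
  to_theta <- function(l) if (logit_link) stats::plogis(l) else l
  lprior_part <- function(l_th, l_t) {
    # log prior of the participant states on the unconstrained scale
    if (hier) {
      pt <- stats::dnorm(l_th, mu_th, sig_th, log = TRUE) +
        stats::dnorm(l_t, mu_t, sig_t, log = TRUE)
    } else {
      pth <- if (logit_link) {
        # Beta(1,1) on alpha: logit-scale density is p(1-p)
        stats::plogis(l_th, log.p = TRUE) + stats::plogis(-l_th, log.p = TRUE)
      } else {
        stats::dnorm(l_th, priors$indep_beta_mean, priors$indep_beta_sd,
                     log = TRUE)
      }
      pt <- pth + stats::dnorm(l_t, priors$indep_logtau_mean,
                               priors$indep_logtau_sd, log = TRUE)
    }
    pt
  }

  ll <- choice_loglik_by_part(dat, model, to_theta(l_th), exp(l_t))
  scale <- rep(0.4, p)
  hscale <- c(0.2, 0.2)
  n_keep <- mcmc$iter
  total <- mcmc$burn + n_keep
  keep_every <- mcmc$thin
  out <- matrix(NA_real_, floor(n_keep / keep_every),
                2 * p + if (hier) 4 else 0)
  colnames(out) <- c(sprintf("theta[%d]", 1:p), sprintf("tau[%d]", 1:p),
                     if (hier) c("mu_th", "sig_th", "mu_t", "sig_t"))
  row <- 0
  for (it in seq_len(total)) {
    # joint 2-D random-walk update per participant, all in one pass
    prop_th <- l_th + stats::rnorm(p) * scale
    prop_t <- l_t + stats::rnorm(p) * scale
    ll_prop <- choice_loglik_by_part(dat, model, to_theta(prop_th), exp(prop_t))
    log_r <- (ll_prop + lprior_part(prop_th, prop_t)) -
      (ll + lprior_part(l_th, l_t))
    acc <- log(stats::runif(p)) < log_r
    l_th[acc] <- prop_th[acc]
    l_t[acc] <- prop_t[acc]
    ll[acc] <- ll_prop[acc]
    if (it <= mcmc$burn) {
      gamma <- 1 / max(20, it)^0.6
      scale <- scale * exp(gamma * (as.numeric(acc) - 0.3))
      scale <- pmin(pmax(scale, 0.01), 5)
    }
    if (hier) {
      # centered step: conjugate locations, slice scales (cheap: P values)
      mu_th <- draw_conj_mean(l_th, sig_th, h$mu_mean, h$mu_sd)
      sig_th <- update_sd(sig_th, p, sum((l_th - mu_th)^2), h$sig_scale)
      mu_t <- draw_conj_mean(l_t, sig_t, priors$mu_logtau_mean,
                             priors$mu_logtau_sd)
      sig_t <- update_sd(sig_t, p, sum((l_t - mu_t)^2),
                         priors$sigma_logtau_scale)
      # interweaved non-centered step: move (mu, sigma) holding the
      # standardized participant deviations fixed, so hyperparameters can
      # travel with the whole population instead of fighting it
      z <- (l_th - mu_th) / sig_th
      mu_p <- mu_th + stats::rnorm(1) * hscale[1]
      ls_p <- log(sig_th) + stats::rnorm(1) * hscale[1]
      l_p <- mu_p + exp(ls_p) * z
      ll_p <- choice_loglik_by_part(dat, model, to_theta(l_p), exp(l_t))
      log_r <- sum(ll_p) - sum(ll) +
        stats::dnorm(mu_p, h$mu_mean, h$mu_sd, log = TRUE) -
        stats::dnorm(mu_th, h$mu_mean, h$mu_sd, log = TRUE) +
        log_halfnormal(exp(ls_p), h$sig_scale) + ls_p -
        log_halfnormal(sig_th, h$sig_scale) - log(sig_th)
      acc_h1 <- log(stats::runif(1)) < log_r
      if (acc_h1) {
        l_th <- l_p
        mu_th <- mu_p
        sig_th <- exp(ls_p)
        ll <- ll_p
      }
      z <- (l_t - mu_t) / sig_t
      mu_p <- mu_t + stats::rnorm(1) * hscale[2]
      ls_p <- log(sig_t) + stats::rnorm(1) * hscale[2]
      l_p <- mu_p + exp(ls_p) * z
      ll_p <- choice_loglik_by_part(dat, model, to_theta(l_th), exp(l_p))
      log_r <- sum(ll_p) - sum(ll) +
        stats::dnorm(mu_p, priors$mu_logtau_mean, priors$mu_logtau_sd,
                     log = TRUE) -
        stats::dnorm(mu_t, priors$mu_logtau_mean, priors$mu_logtau_sd,
                     log = TRUE) +
        log_halfnormal(exp(ls_p), priors$sigma_logtau_scale) + ls_p -
        log_halfnormal(sig_t, priors$sigma_logtau_scale) - log(sig_t)
      acc_h2 <- log(stats::runif(1)) < log_r
      if (acc_h2) {
        l_t <- l_p
        mu_t <- mu_p
        sig_t <- exp(ls_p)
        ll <- ll_p
      }
      if (it <= mcmc$burn) {
        gamma <- 1 / max(20, it)^0.6
        hscale <- pmin(pmax(
          hscale * exp(gamma * (c(acc_h1, acc_h2) - 0.3)), 0.01), 2)
      }
      if (!logit_link) {
        # mean-variance model: the likelihood pins tau * beta, leaving the
        # split between the two scales a slow ridge; propose a joint
        # rescaling beta -> beta e^-d (whole population) with
        # log tau -> log tau + d, which preserves tau * beta exactly
        d <- stats::rnorm(1, 0, 0.15)
        cc <- exp(-d)
        th_p <- l_th * cc
        lt_p <- l_t + d
        ll_p <- choice_loglik_by_part(dat, model, th_p, exp(lt_p))
        log_r <- sum(ll_p) - sum(ll) +
          sum(stats::dnorm(th_p, mu_th * cc, sig_th * cc, log = TRUE) -
                stats::dnorm(l_th, mu_th, sig_th, log = TRUE)) +
          stats::dnorm(mu_th * cc, h$mu_mean, h$mu_sd, log = TRUE) -
          stats::dnorm(mu_th, h$mu_mean, h$mu_sd, log = TRUE) +
          log_halfnormal(sig_th * cc, h$sig_scale) -
          log_halfnormal(sig_th, h$sig_scale) +
          stats::dnorm(mu_t + d, priors$mu_logtau_mean, priors$mu_logtau_sd,
                       log = TRUE) -
          stats::dnorm(mu_t, priors$mu_logtau_mean, priors$mu_logtau_sd,
                       log = TRUE) +
          (p + 2) * log(cc)
        if (log(stats::runif(1)) < log_r) {
          l_th <- th_p
          l_t <- lt_p
          mu_th <- mu_th * cc
          sig_th <- sig_th * cc
          mu_t <- mu_t + d
          ll <- ll_p
        }
      }
    }
    if (it > mcmc$burn && (it - mcmc$burn) %% keep_every == 0) {
      row <- row + 1
      out[row, ] <- c(to_theta(l_th), exp(l_t),
                      if (hier) c(mu_th, sig_th, mu_t, sig_t))
    }
  }
  out
}

# exact draw of a normal location given iid normal observations
draw_conj_mean <- function(x, sd_x, prior_mean, prior_sd) {
  prec <- length(x) / sd_x^2 + 1 / prior_sd^2
  m <- (sum(x) / sd_x^2 + prior_mean / prior_sd^2) / prec
  stats::rnorm(1, m, sqrt(1 / prec))
}
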