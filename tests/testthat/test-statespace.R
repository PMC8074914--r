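# small shared state-space fixture: 6 participants x 12 problems
.ss_env <- new.env()
ss_fixture <- function() {
  if (is.null(.ss_env$fit)) {
    cfg <- small_cfg(n_problems = 12)
    sim <- simulate_experiment(cfg, seed = 51)
    nz <- preprocess_trajectories(sim$trajectories, sim$trials, cfg$geometry)
    spec <- statespace_spec(chains = 2, warmup = 300, iter = 300, seed = 52)
    .ss_env$sim <- sim
    .ss_env$nz <- nz
    .ss_env$spec <- spec
    .ss_env$fit <- fit_statespace(nz, sim$trials, sim$features, spec)
  }
  .ss_env
}

test_that("highest-density intervals behave on known distributions", {
  expect_equal(hdi_interval(rep(3.2, 500)), c(3.2, 3.2))
  set.seed(61)
  z <- rnorm(1e5)
  h <- hdi_interval(z)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  # for symmetric unimodal draws the HDI is close to equal-tailed
  q <- quantile(z, c(0.025, 0.975), names = FALSE)
  expect_lt(max(abs(h - q)), 0.05)
  # skewed draws: HDI is strictly narrower than equal-tailed
  x <- rlnorm(1e5, 0, 0.8)
  hx <- hdi_interval(x)
  qx <- quantile(x, c(0.025, 0.975), names = FALSE)
  expect_lt(diff(hx), diff(qx))
})

test_that("pointwise HDIs work column-wise", {
  set.seed(62)
  d <- cbind(rnorm(5000, 0, 1), rnorm(5000, 3, 0.5))
  pw <- pointwise_hdi(d)
  expect_equal(nrow(pw), 2)
  expect_lt(abs(pw$mean[2] - 3), 0.05)
  expect_true(pw$lower[2] > 1.5 && pw$upper[2] < 4.5)
})

test_that("the simultaneous band contains the pointwise band", {
  set.seed(63)
  d <- matrix(rnorm(2000 * 101), 2000, 101)
  pw <- pointwise_hdi(d)
  sb <- simultaneous_band(d)
  expect_true(all(sb$lower <= pw$lower + 1e-9))
  expect_true(all(sb$upper >= pw$upper - 1e-9))
  # with 101 independent bins multiplicity makes it strictly wider everywhere
  expect_true(all(sb$upper - sb$lower > pw$upper - pw$lower))
  # single time point: matches the pointwise interval for symmetric draws
  d1 <- matrix(rnorm(20000), ncol = 1)
  expect_equal(simultaneous_band(d1)$upper, pointwise_hdi(d1)$upper,
               tolerance = 0.05)
  expect_equal(simultaneous_band(d1)$lower, pointwise_hdi(d1)$lower,
               tolerance = 0.05)
})

test_that("the simultaneous band achieves joint coverage", {
  set.seed(64)
  nt <- 25
  mu <- sin(seq(0, 3, length.out = nt))
  sds <- seq(0.5, 1.5, length.out = nt)
  draws <- sapply(seq_len(nt), function(t) rnorm(3000, mu[t], sds[t]))
  sb <- simultaneous_band(draws)
  fresh <- sapply(seq_len(nt), function(t) rnorm(500, mu[t], sds[t]))
  inside <- vapply(seq_len(500), function(r) {
    all(fresh[r, ] >= sb$lower & fresh[r, ] <= sb$upper)
  }, logical(1))
  expect_gte(mean(inside), 0.95 - 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("departure times read off the first zero-excluding bin", {
  set.seed(65)
  nb <- 101
  dmin <- sapply(seq_len(nb), function(t) {
    rnorm(2000, if (t >= 30) 0.5 else 0, 0.05)
  })
  dmin[, 1] <- 0
  dvar <- sapply(seq_len(nb), function(t) rnorm(2000, 0, 0.05))
  dvar[, 1] <- 0
  rep <- departure_times(list(pop_draws = list(beta_min = dmin, beta_var = dvar)))
  expect_equal(unname(rep$departure["beta_min"]), 30)
  expect_true(is.na(rep$departure["beta_var"]))
  expect_true(all(rep$sign$beta_min[30:101] == 1))
  expect_true(all(rep$min_exceeds_var[30:101]))
  expect_false(any(rep$min_exceeds_var[1:25]))
})

test_that("split R-hat flags disagreeing chains", {
  set.seed(66)
  same <- lapply(1:3, function(i) matrix(rnorm(2000), ncol = 2,
                                         dimnames = list(NULL, c("a", "b"))))
  r <- split_rhat(same)
  expect_true(all(abs(r - 1) < 0.05))
  shifted <- same
  shifted[[2]][, 1] <- shifted[[2]][, 1] + 3
  r2 <- split_rhat(shifted)
  expect_gt(r2["a"], 1.5)
  expect_lt(r2["b"], 1.1)
})

test_that("the state-space fit validates its inputs", {
  env <- ss_fixture()
  bad_feats <- env$sim$features
  bad_feats$z_diff_min <- bad_feats$diff_min # raw, not standardized
  expect_error(
    fit_statespace(env$nz, env$sim$trials, bad_feats, env$spec),
    "standardized"
  )
  expect_error(
    fit_statespace(env$nz[env$nz$bin > 1, ], env$sim$trials,
                   env$sim$features, env$spec),
    "101 bins"
  )
})

test_that("the fitted model pins t = 1 and produces coherent bands", {
  env <- ss_fixture()
  fit <- env$fit
  for (nm in fit$coef_names) {
    expect_true(all(fit$pop_draws[[nm]][, 1] == 0))
    pw <- fit$pointwise[[nm]]
    sb <- fit$simultaneous[[nm]]
    expect_true(all(sb$lower <= pw$lower + 1e-9))
    expect_true(all(sb$upper >= pw$upper - 1e-9))
  }
  expect_true(all(c("sigma_zeta_min", "sigma_eta_min", "sigma_delta") %in%
                    colnames(fit$sd_draws)))
  expect_equal(dim(fit$participant_mean), c(101, 2, 6))
  tab <- coefficients_table(fit)
  expect_equal(nrow(tab), 202)
})

test_that("the posterior is invariant to trial order within participants", {
  env <- ss_fixture()
  set.seed(67)
  perm <- sample(nrow(env$nz))
  fit2 <- fit_statespace(env$nz[perm, ], env$sim$trials, env$sim$features,
                         env$spec)
  expect_equal(fit2$pop_draws$beta_min, env$fit$pop_draws$beta_min)
  expect_equal(fit2$sd_draws, env$fit$sd_draws)
})

test_that("rescaling a raw feature before standardization changes nothing", {
  env <- ss_fixture()
  scaled_problems <- lapply(env$sim$problems, function(p) {
    choice_problem(p$problem_id, p$utilitarian * 2, p$non_utilitarian * 2)
  })
  f2 <- compute_features(scaled_problems)
  fit2 <- fit_statespace(env$nz, env$sim$trials, f2, env$spec)
  expect_equal(fit2$pop_draws$beta_min, env$fit$pop_draws$beta_min)
})

test_that("adding the total covariate adds exactly one population series", {
  env <- ss_fixture()
  spec <- env$spec
  spec$warmup <- 150
  spec$iter <- 150
  fit3 <- fit_statespace_with_total(env$nz, env$sim$trials, env$sim$features,
                                    spec)
  expect_equal(fit3$coef_names, c("beta_min", "beta_var", "beta_total"))
  expect_length(fit3$pop_draws, 3)
  expect_true(all(fit3$pop_draws$beta_total[, 1] == 0))
})

test_that("the random-walk intercept mode also fits", {
  env <- ss_fixture()
  spec <- statespace_spec(mu_dynamics = "random_walk", chains = 2,
                          warmup = 150, iter = 150, seed = 53)
  fit <- fit_statespace(env$nz, env$sim$trials, env$sim$features, spec)
  expect_s3_class(fit, "statespace_fit")
  expect_true(all(fit$pop_draws$beta_min[, 1] == 0))
})

test_that("coefficient plots are built from the fitted bands", {
  env <- ss_fixture()
  p <- plot_coefficients(env$fit)
  expect_s3_class(p, "ggplot")
})
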