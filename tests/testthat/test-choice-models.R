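fast_mcmc <- function() mcmc_control(chains = 2, adapt = 500, burn = 1500, iter = 1500)

test_that("quasi-maximin utility interpolates between minimum and total", {
  p <- c(100, 200, 300)
  expect_equal(utility_quasi_maximin(p, 1), 100)
  expect_equal(utility_quasi_maximin(p, 0), 600)
  expect_equal(utility_quasi_maximin(p, 0.5), 350)
  expect_error(utility_quasi_maximin(p, 1.2), "\\[0, 1\\]")
})

test_that("mean-variance utility penalizes dispersion", {
  p <- c(100, 200, 300)
  expect_equal(utility_mean_variance(p, 0), 200)
  expect_equal(utility_mean_variance(p, 1), 200 - 20000 / 3)
  expect_equal(utility_mean_variance(c(500, 500, 500), 7.3), 500)
})

test_that("the model's utility differences match the utility functions", {
  # the choice rule uses only U(N) - U(U); verify the vectorized predictor
  # path against direct evaluation of the two utilities (scaled by 100)
  probs <- generate_problems(small_cfg(n_problems = 6), seed = 2)
  pred <- alloctrace:::problem_predictors(probs)
  alphas <- c(0.1, 0.6, 0.95)
  duA <- alloctrace:::utility_diff_matrix(pred, alphas, "quasi_maximin")
  betas <- c(-0.4, 0.2, 1.1)
  duB <- alloctrace:::utility_diff_matrix(pred, betas, "mean_variance")
  for (j in seq_along(probs)) {
    n <- probs[[j]]$non_utilitarian
    u <- probs[[j]]$utilitarian
    for (i in seq_along(alphas)) {
      expect_equal(duA[i, j],
                   (utility_quasi_maximin(n, alphas[i]) -
                      utility_quasi_maximin(u, alphas[i])) / 100)
      # order-one beta on the scaled utilities is beta/100 on the yen scale
      expect_equal(duB[i, j],
                   (utility_mean_variance(n, betas[i] / 100) -
                      utility_mean_variance(u, betas[i] / 100)) / 100)
    }
  }
})

test_that("a consistent maximin agent's alpha is recovered", {
  cfg <- sim_config(n_participants = 1, n_problems = 48,
                    alpha_mean = 0.9, alpha_sd = 0,
                    tau_meanlog = log(30), tau_sdlog = 0)
  probs <- generate_problems(cfg, seed = 15)
  tr <- simulate_choices(probs, cfg, seed = 16)
  fit <- fit_choice_model(tr, probs, "quasi_maximin", mode = "independent",
                          mcmc = fast_mcmc(), seed = 17)
  expect_lt(abs(fit$participants$mean - 0.9), 0.1)
  expect_true(fit$converged)
})

test_that("an always-N participant gets an upper-range alpha posterior", {
  probs <- generate_problems(small_cfg(), seed = 3)
  tr <- data.frame(
    participant_id = "s01", problem_id = vapply(probs, `[[`, "", "problem_id"),
    trial_index = seq_along(probs),
    side_of_non_utilitarian = "right", choice = "N", rt = 2
  )
  fit <- fit_choice_model(tr, probs, "quasi_maximin", mode = "independent",
                          mcmc = fast_mcmc(), seed = 18)
  expect_gt(fit$participants$mean, 0.6)
  expect_gt(fit$participants$lower, 0.5)
})

test_that("hierarchical fits of both models converge on a small experiment", {
  e <- small_experiment()
  for (m in c("quasi_maximin", "mean_variance")) {
    fit <- fit_choice_model(e$trials, e$problems, m, mcmc = fast_mcmc(),
                            seed = 19)
    expect_true(fit$converged)
    expect_equal(nrow(fit$participants), 6)
    expect_true(all(fit$rhat < 1.1, na.rm = TRUE))
    if (m == "quasi_maximin") {
      expect_true(all(fit$participants$mean >= 0 & fit$participants$mean <= 1))
    }
  }
})

test_that("the choice-rate intercept recovers a 73% non-Utilitarian split", {
  set.seed(31)
  np <- 36
  nj <- 48
  p_i <- plogis(rnorm(np, qlogis(0.73), 0.4))
  tr <- data.frame(
    participant_id = rep(sprintf("s%02d", 1:np), each = nj),
    choice = ifelse(rbinom(np * nj, 1, rep(p_i, each = nj)) == 1, "N", "U")
  )
  fit <- fit_choice_rate(tr, mcmc = fast_mcmc(), seed = 32)
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept - qlogis(0.73)), 0.45)
  expect_gt(fit$ci[1], 0) # strong preference: interval excludes zero
  # balanced choices: interval covers zero
  tr50 <- tr
  set.seed(33)
  tr50$choice <- ifelse(rbinom(np * nj, 1, 0.5) == 1, "N", "U")
  fit50 <- fit_choice_rate(tr50, mcmc = fast_mcmc(), seed = 34)
  expect_lt(fit50$ci[1], 0)
  expect_gt(fit50$ci[2], 0)
})

test_that("the response-time model detects a real penalty and not a null", {
  set.seed(41)
  np <- 36
  nj <- 48
  pid <- rep(sprintf("s%02d", 1:np), each = nj)
  isn <- rbinom(np * nj, 1, 0.7)
  base <- rep(rnorm(np, 2, 0.3), each = nj)
  # +0.3 s penalty for Utilitarian choices
  rt1 <- base + 0.3 * (1 - isn) + rnorm(np * nj, 0, 0.5)
  tr1 <- data.frame(participant_id = pid, choice = ifelse(isn == 1, "N", "U"),
                    rt = rt1)
  fit1 <- fit_rt_model(tr1, mcmc = fast_mcmc(), seed = 42)
  expect_lt(fit1$ci[2], 0) # N faster, so the N coefficient is negative
  # no true difference: interval covers zero
  tr0 <- tr1
  set.seed(43)
  tr0$rt <- base + rnorm(np * nj, 0, 0.5)
  fit0 <- fit_rt_model(tr0, mcmc = fast_mcmc(), seed = 44)
  expect_lt(fit0$ci[1], 0)
  expect_gt(fit0$ci[2], 0)
  expect_error(fit_rt_model(tr1[tr1$choice == "N", ]), "both choice types")
})
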