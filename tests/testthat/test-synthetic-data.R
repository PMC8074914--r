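test_that("generated problem sets satisfy the dominance invariants", {
  for (s in 1:5) {
    probs <- generate_problems(small_cfg(n_problems = 12), seed = s)
    expect_length(probs, 12)
    for (p in probs) {
      expect_gt(p$summary_u$total, p$summary_n$total)
      expect_gt(p$summary_n$min, p$summary_u$min)
      expect_lt(p$summary_n$gini, p$summary_u$gini)
      expect_true(all(p$utilitarian >= 0), all(p$non_utilitarian >= 0))
    }
  }
})

test_that("the realized feature correlation lands in the target band", {
  cfg <- sim_config() # 48 problems, target 0.49 +/- 0.1
  probs <- generate_problems(cfg, seed = 42)
  expect_length(probs, 48)
  r <- feature_correlation(compute_features(probs))
  expect_gte(r, 0.39)
  expect_lte(r, 0.59)
})

test_that("tiny problem sets skip the correlation constraint", {
  probs <- generate_problems(small_cfg(n_problems = 2), seed = 1)
  expect_length(probs, 2)
})

test_that("an unsatisfiable correlation target fails loudly", {
  cfg <- small_cfg(n_problems = 12, target_feature_correlation = -0.9,
                   rejection_budget = 5)
  expect_error(generate_problems(cfg, seed = 1), "correlation")
})

test_that("the whole experiment is reproducible under a fixed seed", {
  e1 <- simulate_experiment(small_cfg(), seed = 7)
  e2 <- simulate_experiment(small_cfg(), seed = 7)
  expect_identical(e1$trials, e2$trials)
  expect_identical(e1$trajectories, e2$trajectories)
  expect_identical(problems_table(e1$problems), problems_table(e2$problems))
  e3 <- simulate_experiment(small_cfg(), seed = 8)
  expect_false(identical(e1$trials$choice, e3$trials$choice))
})

test_that("agents at the utility-model limits choose deterministically", {
  probs <- generate_problems(small_cfg(), seed = 3)
  # pure maximin, near-deterministic choice: always N
  cfg_max <- small_cfg(alpha_mean = 1, alpha_sd = 0,
                       tau_meanlog = log(500), tau_sdlog = 0)
  tr <- simulate_choices(probs, cfg_max, seed = 4)
  expect_true(all(tr$choice == "N"))
  # pure total-maximizer: always U
  cfg_tot <- small_cfg(alpha_mean = 0, alpha_sd = 0,
                       tau_meanlog = log(500), tau_sdlog = 0)
  tr <- simulate_choices(probs, cfg_tot, seed = 4)
  expect_true(all(tr$choice == "U"))
})

test_that("trial bookkeeping is complete and response times positive", {
  e <- small_experiment()
  tr <- e$trials
  expect_true(all(tr$rt > 0))
  expect_true(all(tr$side_of_non_utilitarian %in% c("left", "right")))
  # each participant sees each problem exactly once
  tab <- table(tr$participant_id, tr$problem_id)
  expect_true(all(tab == 1))
  # presentation order differs across participants (randomized)
  ord <- split(tr$problem_id[order(tr$participant_id, tr$trial_index)],
               tr$participant_id[order(tr$participant_id, tr$trial_index)])
  expect_gt(length(unique(vapply(ord, paste, character(1), collapse = ","))), 1)
})

test_that("the default agent population brackets the observed choice split", {
  cfg <- sim_config() # 36 x 48, defaults
  probs <- generate_problems(cfg, seed = 5)
  tr <- simulate_choices(probs, cfg, seed = 6)
  rate <- mean(tr$choice == "N")
  expect_gte(rate, 0.6)
  expect_lte(rate, 0.85)
})

test_that("the non-Utilitarian choice rate rises with the alpha mean", {
  probs <- generate_problems(small_cfg(n_problems = 24), seed = 9)
  rates <- vapply(c(0.3, 0.6, 0.9), function(am) {
    cfg <- small_cfg(n_problems = 24, n_participants = 30, alpha_mean = am,
                     alpha_sd = 0.05)
    mean(simulate_choices(probs, cfg, seed = 10)$choice == "N")
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("trajectories start at the start button and end on the chosen target", {
  e <- small_experiment()
  g <- e$config$geometry
  sp <- split(e$trajectories, paste(e$trajectories$participant_id,
                                    e$trajectories$trial_index))
  tkey <- paste(e$trials$participant_id, e$trials$trial_index)
  for (k in names(sp)[1:20]) {
    tt <- sp[[k]]
    expect_true(all(diff(tt$t_ms) > 0))
    expect_equal(c(tt$x_px[1], tt$y_px[1]), g$start, tolerance = 1e-6)
    row <- match(k, tkey)
    target <- if ((e$trials$choice[row] == "N") ==
                  (e$trials$side_of_non_utilitarian[row] == "right")) {
      g$right
    } else {
      g$left
    }
    n <- nrow(tt)
    expect_equal(c(tt$x_px[n], tt$y_px[n]), target, tolerance = 1e-6)
  }
})

test_that("a positive minimum coefficient pulls x toward the non-Utilitarian side", {
  # two matched simulations: null series vs a step in the minimum series;
  # mean mid-trajectory x on high-|dmin| trials must be larger under the step
  base <- small_cfg(n_participants = 20, n_problems = 10,
                    beta_min_series = rep(0, 101), beta_var_series = rep(0, 101),
                    sigma_eta_min = 0, sigma_eta_var = 0, sigma_delta = 0)
  step <- base
  step$beta_min_series <- c(rep(0, 29), rep(0.2, 72))
  probs <- generate_problems(base, seed = 12)
  feats <- compute_features(probs)
  tr <- simulate_choices(probs, base, seed = 13)
  hi <- feats$problem_id[feats$z_diff_min > 0.5]
  mid_x <- function(cfg) {
    traj <- simulate_trajectories(tr, feats, cfg, seed = 14)
    nz <- preprocess_trajectories(traj, tr, cfg$geometry)
    mean(nz$x[nz$bin == 60 & paste(nz$participant_id, nz$trial_index) %in%
                paste(tr$participant_id, tr$trial_index)[tr$problem_id %in% hi]])
  }
  expect_gt(mid_x(step), mid_x(base) + 0.05)
})

test_that("too-short response times are rejected", {
  e <- small_experiment()
  tr <- e$trials[1, , drop = FALSE]
  tr$rt <- 0.001 # under two samples at 60 Hz
  expect_error(simulate_trajectories(tr, e$features, e$config, seed = 1),
               "two cursor samples")
})
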