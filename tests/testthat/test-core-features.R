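# brute-force oracle: relative mean absolute pairwise difference
gini_oracle <- function(p) {
  s <- 0
  for (i in 1:3) for (j in 1:3) s <- s + abs(p[i] - p[j])
  s / (2 * 3^2 * mean(p))
}

test_that("Gini coefficient matches its definition and known values", {
  expect_equal(gini(c(500, 500, 500)), 0)
  expect_equal(gini(c(0, 0, 900)), 2 / 3)
  expect_equal(gini(c(100, 200, 300)), gini_oracle(c(100, 200, 300)))
  expect_equal(gini(c(100, 200, 300)), 800 / (2 * 9 * 200))
  set.seed(11)
  for (k in 1:25) {
    p <- round(runif(3, 0, 1500))
    if (mean(p) == 0) next
    expect_equal(gini(p), gini_oracle(p))
  }
  expect_error(gini(c(0, 0, 0)), "undefined")
  expect_error(gini(c(-1, 5, 5)), "non-negative")
  expect_error(gini(c(1, 2)), "three")
})

test_that("Gini is scale- and permutation-invariant and bounded by 2/3", {
  set.seed(21)
  for (k in 1:30) {
    p <- runif(3, 0, 1000) + 1
    expect_equal(gini(3.7 * p), gini(p))
    expect_equal(gini(p * 0.01), gini(p))
    expect_equal(gini(sample(p)), gini(p))
    g <- gini(p)
    expect_gte(g, 0)
    expect_lte(g, 2 / 3)
  }
})

test_that("payoff variance uses the population divisor by default", {
  expect_equal(payoff_variance(c(500, 500, 500)), 0)
  expect_equal(payoff_variance(c(100, 200, 300)), 20000 / 3)
  expect_equal(payoff_variance(c(0, 0, 900)), 180000)
  expect_equal(payoff_variance(c(100, 200, 300), divisor = "sample"),
               var(c(100, 200, 300)))
  set.seed(5)
  p <- runif(3, 0, 900)
  expect_equal(payoff_variance(sample(p)), payoff_variance(p))
})

test_that("choice problems enforce both dominance relations", {
  expect_s3_class(example_problem(), "choice_problem")
  # N must not have the larger total
  expect_error(choice_problem("x", c(500, 700, 900), c(80, 1010, 1210)),
               "larger total")
  # equal minima are not allowed
  expect_error(choice_problem("x", c(500, 600, 1200), c(500, 700, 900)),
               "larger minimum")
})

test_that("difference predictors reproduce the worked example and standardize", {
  probs <- c(list(example_problem()),
             generate_problems(small_cfg(n_problems = 15), seed = 8))
  f <- compute_features(probs)
  ex <- f[f$problem_id == "ex", ]
  expect_equal(ex$diff_min, 420)
  expect_equal(ex$diff_var, 0.2, tolerance = 0.005)
  expect_equal(ex$diff_total, 200)
  for (col in c("z_diff_min", "z_diff_var", "z_diff_total")) {
    expect_lt(abs(mean(f[[col]])), 1e-9)
    expect_lt(abs(mean(f[[col]]^2) - 1), 1e-9)
  }
  # raw differences are non-negative and match the option summaries
  for (p in probs) {
    row <- f[f$problem_id == p$problem_id, ]
    expect_equal(row$diff_min, p$summary_n$min - p$summary_u$min)
    expect_equal(row$diff_var, p$summary_u$gini - p$summary_n$gini)
    expect_gte(row$diff_total, 0)
  }
  expect_error(compute_features(probs[1]), "at least 2")
})

test_that("standardized predictors absorb the pay-off scale", {
  probs <- generate_problems(small_cfg(n_problems = 10), seed = 6)
  scaled <- lapply(probs, function(p) {
    choice_problem(p$problem_id, p$utilitarian * 4, p$non_utilitarian * 4)
  })
  f1 <- compute_features(probs)
  f2 <- compute_features(scaled)
  expect_equal(f2$diff_min, 4 * f1$diff_min)
  expect_equal(f2$diff_var, f1$diff_var) # Gini is scale-free
  for (col in c("z_diff_min", "z_diff_var", "z_diff_total")) {
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-12)
  }
})

test_that("feature correlation behaves on exact and degenerate inputs", {
  f <- data.frame(diff_min = c(1, 3, 7, 2), diff_var = 2 * c(1, 3, 7, 2))
  expect_equal(feature_correlation(f), 1)
  f$diff_var <- -0.5 * f$diff_min
  expect_equal(feature_correlation(f), -1)
  expect_error(feature_correlation(data.frame(diff_min = c(1, 2), diff_var = c(1, 2))),
               "at least 3")
  expect_error(feature_correlation(data.frame(diff_min = c(1, 1, 1),
                                              diff_var = c(1, 2, 3))),
               "constant")
})

test_that("problems round-trip through the table representation", {
  probs <- generate_problems(small_cfg(n_problems = 6), seed = 2)
  tab <- problems_table(probs)
  expect_equal(nrow(tab), 12)
  back <- problems_from_table(tab)
  expect_equal(problems_table(back), tab)
})
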