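# Small shared fixtures, generated once per test run.

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_participants = 6, n_problems = 16),
                            list(...))
  do.call(sim_config, args)
}

# cached small experiment used by several test files
.fixture_env <- new.env()

small_experiment <- function() {
  if (is.null(.fixture_env$exp)) {
    .fixture_env$exp <- simulate_experiment(small_cfg(), seed = 3)
  }
  .fixture_env$exp
}

# a deterministic hand-built problem pair: minima differ by 420 yen and
# Gini coefficients by about 0.2 (the magnitudes shown on the task screen)
example_problem <- function() {
  choice_problem(
    "ex",
    utilitarian = c(80, 1010, 1210), # min 80, total 2300, Gini 0.3275
    non_utilitarian = c(500, 700, 900) # min 500, total 2100, Gini 0.1270
  )
}
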