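#' Smooth onset ramp for a population coefficient series
#'
#' Zero before `onset`, half-cosine ramp from `onset` to `peak`, then
#' constant at `level`. Used to define generating coefficient series over
#' the 101 normalized time bins.
#'
#' @param onset first bin at which the series departs from zero.
#' @param peak bin at which the ramp reaches `level`.
#' @param level plateau value (normalized-x units per SD of the predictor).
#' @param n_bins number of time bins (101).
#' @return numeric vector of length `n_bins`.
#' @export
ramp_series <- function(onset, peak, level, n_bins = 101) {
  stopifnot(onset >= 2, peak > onset, peak <= n_bins)
  t <- seq_len(n_bins)
  out <- numeric(n_bins)
  ramp <- t >= onset & t <= peak
  out[ramp] <- level * (1 - cos(pi * (t[ramp] - onset) / (peak - onset))) / 2
  out[t > peak] <- level
  out
}

#' Configuration for the synthetic experiment generator
#'
#' Defaults reproduce the structure of the allocation task: 36 participants,
#' 48 choice problems, 60 Hz cursor sampling, a target Pearson correlation
#' of 0.49 between the minimum and Gini difference predictors, quasi-maximin
#' agents with population mean alpha 0.85 (SD 0.1, clipped to the unit
#' interval), inverse temperatures calibrated so that about 73% of simulated
#' choices are non-Utilitarian, and log-normal response times with mean
#' around 2 s. Trajectories follow the same state-space process the analysis
#' fits: population coefficient series for the minimum and Gini predictors
#' (ramping up from bins 29 and 50 by default), participant-level deviations,
#' a per-participant linear intercept drift, and Gaussian observation noise
#' with SD 0.005.
#'
#' @param n_participants,n_problems,sampling_rate_hz experiment dimensions.
#' @param target_feature_correlation,correlation_tolerance target band for
#'   the realized correlation between `diff_min` and `diff_var`; the
#'   constraint is skipped below `correlation_min_problems` problems, where
#'   a sample correlation is too unstable to constrain.
#' @param rejection_budget maximum number of whole-set redraws.
#' @param agent_model `"quasi_maximin"` or `"mean_variance"` generative
#'   preferences.
#' @param alpha_mean,alpha_sd population distribution of the maximin weight
#'   (normal, clipped to `[0, 1]`).
#' @param beta_mean,beta_sd population distribution of the egalitarian
#'   weight (on utilities scaled to 100-yen units).
#' @param tau_meanlog,tau_sdlog log-normal inverse-temperature distribution.
#' @param rt_meanlog,rt_sdlog log-normal response-time distribution (s).
#' @param base_range,n_spread_max,dmin_range,dtot_range,gini_gap_range
#'   pay-off construction ranges (yen; Gini gap dimensionless).
#' @param beta_min_series,beta_var_series,beta_total_series true population
#'   coefficient series (length 101; total series `NULL` to omit).
#' @param sigma_delta SD of the per-participant intercept drift per bin.
#' @param sigma_eta_min,sigma_eta_var SD of participant deviations around the
#'   population coefficient series.
#' @param obs_noise_sd observation noise SD in normalized x units.
#' @param geometry screen geometry, see [make_geometry()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 36,
                       n_problems = 48,
                       sampling_rate_hz = 60,
                       target_feature_correlation = 0.49,
                       correlation_tolerance = 0.1,
                       correlation_min_problems = 5,
                       rejection_budget = 200,
                       agent_model = c("quasi_maximin", "mean_variance"),
                       alpha_mean = 0.85, alpha_sd = 0.10,
                       beta_mean = 0.30, beta_sd = 0.15,
                       tau_meanlog = log(0.5), tau_sdlog = 0.6,
                       rt_meanlog = log(1.8), rt_sdlog = 0.5,
                       base_range = c(400, 700),
                       n_spread_max = 120,
                       dmin_range = c(120, 550),
                       dtot_range = c(100, 500),
                       gini_gap_range = c(0.04, 0.34),
                       beta_min_series = ramp_series(29, 70, 0.15),
                       beta_var_series = ramp_series(50, 85, 0.05),
                       beta_total_series = NULL,
                       sigma_delta = 0.003,
                       sigma_eta_min = 0.05,
                       sigma_eta_var = 0.05,
                       obs_noise_sd = 0.005,
                       geometry = make_geometry()) {
  agent_model <- match.arg(agent_model)
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_participants >= 1, cfg$n_problems >= 2, cfg$sampling_rate_hz > 0,
    cfg$alpha_sd >= 0, cfg$beta_sd >= 0, cfg$sigma_delta >= 0,
    cfg$sigma_eta_min >= 0, cfg$sigma_eta_var >= 0, cfg$obs_noise_sd >= 0,
    length(cfg$beta_min_series) == 101, length(cfg$beta_var_series) == 101
  )
  class(cfg) <- "sim_config"
  cfg
}

# draw one choice problem satisfying both dominance relations, with the
# Gini gap drawn independently of the minimum gap (decorrelates the two
# difference predictors; the residual correlation comes from feasibility)
draw_problem <- function(id, cfg) {
  for (it in 1:400) {
    base <- round(stats::runif(1, cfg$base_range[1], cfg$base_range[2]) / 10) * 10
    dn <- sort(round(stats::runif(2, 0, cfg$n_spread_max) / 10) * 10)
    n_opt <- c(base, base + dn[1], base + dn[2])
    g_n <- gini(n_opt)
    dmin <- round(stats::runif(1, cfg$dmin_range[1], cfg$dmin_range[2]) / 10) * 10
    dtot <- round(stats::runif(1, cfg$dtot_range[1], cfg$dtot_range[2]) / 10) * 10
    min_u <- base - dmin
    if (min_u < 0) next
    tot_u <- sum(n_opt) + dtot
    g_target <- g_n + stats::runif(1, cfg$gini_gap_range[1], cfg$gini_gap_range[2])
    f <- function(x) gini(c(min_u, x, tot_u - min_u - x)) - g_target
    lo <- min_u
    hi <- (tot_u - min_u) / 2
    if (f(lo) < 0 || f(hi) > 0) next # target Gini infeasible for this triple
    mid_u <- round(stats::uniroot(f, c(lo, hi))$root / 10) * 10
    u_opt <- c(min_u, mid_u, tot_u - min_u - mid_u)
    if (any(u_opt < 0) || is.unsorted(u_opt)) next
    ok <- tryCatch(
      {
        choice_problem(id, utilitarian = u_opt, non_utilitarian = n_opt)
      },
      error = function(e) NULL
    )
    if (!is.null(ok)) return(ok)
  }
  NULL
}

#' Generate a set of choice problems
#'
#' Draws pay-off triples until every problem satisfies both dominance
#' relations (Utilitarian option: larger total; non-Utilitarian option:
#' larger minimum and smaller Gini) and, for sets of at least
#' `correlation_min_problems` problems, until the realized Pearson
#' correlation between `diff_min` and `diff_var` falls within
#' `correlation_tolerance` of `target_feature_correlation` (whole-set
#' rejection sampling).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of [choice_problem()] objects.
#' @export
generate_problems <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  check_cor <- config$n_problems >= config$correlation_min_problems
  for (attempt in seq_len(config$rejection_budget)) {
    probs <- lapply(seq_len(config$n_problems), function(k) {
      draw_problem(sprintf("p%02d", k), config)
    })
    if (any(vapply(probs, is.null, logical(1)))) {
      stop(
        "problem generation failed: could not satisfy the dominance and ",
        "Gini-gap constraints within the per-problem attempt budget"
      )
    }
    if (!check_cor) return(probs)
    r <- feature_correlation(compute_features(probs))
    if (abs(r - config$target_feature_correlation) <= config$correlation_tolerance) {
      return(probs)
    }
  }
  stop(
    "problem generation failed: realized feature correlation never entered ",
    sprintf(
      "%.2f +/- %.2f within the rejection budget",
      config$target_feature_correlation, config$correlation_tolerance
    )
  )
}

#' Simulate participants' choices and response times
#'
#' Each participant's preference parameters are drawn from the configured
#' population distributions; on every trial the participant chooses the
#' non-Utilitarian option with probability
#' `logistic(tau * (U(N) - U(U)))` under the configured utility model
#' (softmax over the two options). Presentation side of the non-Utilitarian
#' option and problem order are randomized per participant; response times
#' are log-normal.
#'
#' @param problems list of [choice_problem()] objects.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame with one row per trial: `participant_id`,
#'   `problem_id`, `trial_index`, `side_of_non_utilitarian`, `choice`
#'   (`"U"`/`"N"`), `rt` (s). The generating agent parameters are attached
#'   as attribute `"agents"`.
#' @export
simulate_choices <- function(problems, config = sim_config(), seed = 1) {
  set.seed(seed)
  np <- config$n_participants
  nj <- length(problems)
  pred <- problem_predictors(problems)
  if (config$agent_model == "quasi_maximin") {
    theta <- pmin(pmax(stats::rnorm(np, config$alpha_mean, config$alpha_sd), 0), 1)
  } else {
    theta <- stats::rnorm(np, config$beta_mean, config$beta_sd)
  }
  tau <- stats::rlnorm(np, config$tau_meanlog, config$tau_sdlog)
  du <- utility_diff_matrix(pred, theta, config$agent_model)
  p_n <- stats::plogis(du * tau)
  rows <- lapply(seq_len(np), function(i) {
    ord <- sample.int(nj) # presentation order of problems
    choice <- ifelse(stats::rbinom(nj, 1, p_n[i, ord]) == 1, "N", "U")
    data.frame(
      participant_id = sprintf("s%02d", i),
      problem_id = pred$problem_id[ord],
      trial_index = seq_len(nj),
      side_of_non_utilitarian = sample(c("left", "right"), nj, replace = TRUE),
      choice = choice,
      rt = stats::rlnorm(nj, config$rt_meanlog, config$rt_sdlog),
      stringsAsFactors = FALSE
    )
  })
  trials <- do.call(rbind, rows)
  agents <- data.frame(
    participant_id = sprintf("s%02d", seq_len(np)),
    theta = theta, tau = tau, stringsAsFactors = FALSE
  )
  names(agents)[2] <- if (config$agent_model == "quasi_maximin") "alpha" else "beta"
  attr(trials, "agents") <- agents
  trials
}

#' Simulate 60 Hz cursor trajectories from the state-space process
#'
#' Generates, for every trial, the 101-bin latent path in analysis
#' coordinates from the configured true population coefficient series
#' (plus participant deviations, per-participant intercept drift and
#' observation noise), pins bin 1 to (0, 0) and bin 101 to the chosen
#' option's target, maps the path to screen pixels (flipping x when the
#' non-Utilitarian option was shown on the left) and resamples it onto the
#' 60 Hz clock over the trial's response time. The y coordinate rises
#' monotonically from start to target.
#'
#' @param trials data.frame from [simulate_choices()].
#' @param features data.frame from [compute_features()] for the same
#'   problems.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return long data.frame: `participant_id`, `trial_index`, `t_ms`,
#'   `x_px`, `y_px`. The generating participant-level series are attached
#'   as attribute `"traj_truth"`.
#' @export
simulate_trajectories <- function(trials, features, config = sim_config(), seed = 1) {
  set.seed(seed)
  if (!all(trials$problem_id %in% features$problem_id)) {
    stop("every trial's problem must be present in the feature table")
  }
  ids <- unique(trials$participant_id)
  np <- length(ids)
  nb <- 101
  with_total <- !is.null(config$beta_total_series)
  delta <- stats::rnorm(np, 0, config$sigma_delta)
  b_min <- matrix(config$beta_min_series, nb, np) +
    rbind(0, matrix(stats::rnorm((nb - 1) * np, 0, config$sigma_eta_min), nb - 1, np))
  b_var <- matrix(config$beta_var_series, nb, np) +
    rbind(0, matrix(stats::rnorm((nb - 1) * np, 0, config$sigma_eta_var), nb - 1, np))
  if (with_total) {
    b_tot <- matrix(config$beta_total_series, nb, np) +
      rbind(0, matrix(stats::rnorm((nb - 1) * np, 0, config$sigma_eta_var), nb - 1, np))
  }
  fidx <- match(trials$problem_id, features$problem_id)
  pidx <- match(trials$participant_id, ids)
  dt_ms <- 1000 / config$sampling_rate_hz
  out <- vector("list", nrow(trials))
  for (k in seq_len(nrow(trials))) {
    i <- pidx[k]
    x <- (seq_len(nb) - 1) * delta[i] +
      b_min[, i] * features$z_diff_min[fidx[k]] +
      b_var[, i] * features$z_diff_var[fidx[k]] +
      c(0, stats::rnorm(nb - 1, 0, config$obs_noise_sd))
    if (with_total) x <- x + b_tot[, i] * features$z_diff_total[fidx[k]]
    x[1] <- 0
    x[nb] <- if (trials$choice[k] == "N") 1 else -1
    y <- seq(0, 1, length.out = nb)
    rt_ms <- trials$rt[k] * 1000
    t_raw <- seq(0, rt_ms, by = dt_ms)
    if (length(t_raw) < 2) {
      stop("response time shorter than two cursor samples at the configured rate")
    }
    if (t_raw[length(t_raw)] < rt_ms) t_raw <- c(t_raw, rt_ms)
    t_bins <- seq(0, rt_ms, length.out = nb)
    xr <- stats::approx(t_bins, x, xout = t_raw)$y
    yr <- stats::approx(t_bins, y, xout = t_raw)$y
    # analysis x is positive toward the non-Utilitarian option; on screen the
    # left target is x = -1, so flip when N was presented on the left
    if (trials$side_of_non_utilitarian[k] == "left") xr <- -xr
    px <- analysis_to_pixels(cbind(xr, yr), config$geometry)
    out[[k]] <- data.frame(
      participant_id = trials$participant_id[k],
      trial_index = trials$trial_index[k],
      t_ms = t_raw, x_px = px[, 1], y_px = px[, 2],
      stringsAsFactors = FALSE
    )
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  attr(traj, "traj_truth") <- list(
    delta = delta, beta_min = b_min, beta_var = b_var,
    beta_tot = if (with_total) b_tot else NULL,
    beta_min_series = config$beta_min_series,
    beta_var_series = config$beta_var_series,
    beta_total_series = config$beta_total_series
  )
  traj
}

#' Simulate a complete experiment
#'
#' Runs [generate_problems()], [compute_features()], [simulate_choices()]
#' and [simulate_trajectories()] under sub-seeds derived from one seed, and
#' collects the generating truth for recovery studies.
#'
#' @param config a [sim_config()].
#' @param seed integer seed governing the whole experiment.
#' @return list with elements `problems`, `features`, `trials`,
#'   `trajectories`, `truth` and `config`.
#' @export
simulate_experiment <- function(config = sim_config(), seed = 1) {
  problems <- generate_problems(config, seed = seed)
  features <- compute_features(problems)
  trials <- simulate_choices(problems, config, seed = seed + 1L)
  trajectories <- simulate_trajectories(trials, features, config, seed = seed + 2L)
  list(
    problems = problems, features = features, trials = trials,
    trajectories = trajectories,
    truth = list(
      agents = attr(trials, "agents"),
      trajectory = attr(trajectories, "traj_truth"),
      feature_correlation = feature_correlation(features),
      seed = seed
    ),
    config = config
  )
}
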