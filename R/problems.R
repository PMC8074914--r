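#' Construct a choice problem
#'
#' A choice problem pairs a Utilitarian option (larger total) with a
#' non-Utilitarian option (larger minimum pay-off and smaller Gini
#' coefficient). Both dominance relations are enforced.
#'
#' @param problem_id identifier (coerced to character).
#' @param utilitarian,non_utilitarian numeric vectors of three pay-offs (yen).
#' @return an object of class `choice_problem`: a list with the two
#'   allocations and their summaries.
#' @export
choice_problem <- function(problem_id, utilitarian, non_utilitarian) {
  su <- allocation_summary(utilitarian)
  sn <- allocation_summary(non_utilitarian)
  if (!(su$total > sn$total)) {
    stop("the Utilitarian option must have the larger total")
  }
  if (!(sn$min > su$min)) {
    stop("the non-Utilitarian option must have the larger minimum pay-off")
  }
  if (!(sn$gini < su$gini)) {
    stop("the non-Utilitarian option must have the smaller Gini coefficient")
  }
  structure(
    list(
      problem_id = as.character(problem_id),
      utilitarian = utilitarian, non_utilitarian = non_utilitarian,
      summary_u = su, summary_n = sn
    ),
    class = "choice_problem"
  )
}

#' @export
print.choice_problem <- function(x, ...) {
  cat(sprintf(
    "choice problem %s\n  U: %s (min %g, Gini %.3f, total %g)\n  N: %s (min %g, Gini %.3f, total %g)\n",
    x$problem_id,
    paste(x$utilitarian, collapse = "/"), x$summary_u$min, x$summary_u$gini, x$summary_u$total,
    paste(x$non_utilitarian, collapse = "/"), x$summary_n$min, x$summary_n$gini, x$summary_n$total
  ))
  invisible(x)
}

#' Tabulate a list of choice problems
#'
#' Two rows per problem (`option` is `"U"` or `"N"`), with sorted pay-offs
#' and the summaries shown to participants.
#'
#' @param problems list of [choice_problem()] objects.
#' @return data.frame with columns `problem_id`, `option`, `pay_min`,
#'   `pay_med`, `pay_high`, `gini`, `total`.
#' @export
problems_table <- function(problems) {
  stopifnot(length(problems) >= 1)
  do.call(rbind, lapply(problems, function(p) {
    data.frame(
      problem_id = p$problem_id,
      option = c("U", "N"),
      pay_min = c(p$summary_u$min, p$summary_n$min),
      pay_med = c(p$summary_u$med, p$summary_n$med),
      pay_high = c(p$summary_u$high, p$summary_n$high),
      gini = c(p$summary_u$gini, p$summary_n$gini),
      total = c(p$summary_u$total, p$summary_n$total),
      stringsAsFactors = FALSE
    )
  }))
}

#' Rebuild choice problems from a problems table
#'
#' Inverse of [problems_table()]; accepts a data.frame or a CSV path.
#'
#' @param x data.frame in the [problems_table()] layout, or a file path.
#' @return list of [choice_problem()] objects.
#' @export
problems_from_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("problem_id", "option", "pay_min", "pay_med", "pay_high")
  if (!all(need %in% names(x))) {
    stop("problems table needs columns: ", paste(need, collapse = ", "))
  }
  ids <- unique(x$problem_id)
  lapply(ids, function(id) {
    rows <- x[x$problem_id == id, ]
    u <- rows[rows$option == "U", ]
    n <- rows[rows$option == "N", ]
    if (nrow(u) != 1 || nrow(n) != 1) stop("problem ", id, " needs one U and one N row")
    choice_problem(id,
      utilitarian = as.numeric(u[c("pay_min", "pay_med", "pay_high")]),
      non_utilitarian = as.numeric(n[c("pay_min", "pay_med", "pay_high")])
    )
  })
}

# standardize to mean 0 and (population) variance exactly 1
standardize_col <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("cannot standardize a constant column")
  (x - mean(x)) / s
}

#' Between-option difference predictors for a problem set
#'
#' For each problem computes the absolute between-option differences used as
#' trajectory predictors: `diff_min = |min_N - min_U|` (yen), `diff_var =
#' |Gini_N - Gini_U|` (dimensionless; the "variance" summary shown to
#' participants is a Gini coefficient) and `diff_total = |total_U - total_N|`
#' (yen). Each column is also standardized to mean zero and variance one
#' across the problem set (population divisor), so that regression
#' coefficients on the different predictors are comparable in magnitude.
#'
#' @param problems list of [choice_problem()] objects (at least 2).
#' @return data.frame with columns `problem_id`, `diff_min`, `diff_var`,
#'   `diff_total` and their standardized versions `z_diff_min`, `z_diff_var`,
#'   `z_diff_total`.
#' @export
compute_features <- function(problems) {
  if (length(problems) < 2) {
    stop("standardization needs at least 2 problems")
  }
  f <- do.call(rbind, lapply(problems, function(p) {
    data.frame(
      problem_id = p$problem_id,
      diff_min = abs(p$summary_n$min - p$summary_u$min),
      diff_var = abs(p$summary_n$gini - p$summary_u$gini),
      diff_total = abs(p$summary_u$total - p$summary_n$total),
      stringsAsFactors = FALSE
    )
  }))
  f$z_diff_min <- standardize_col(f$diff_min)
  f$z_diff_var <- standardize_col(f$diff_var)
  f$z_diff_total <- standardize_col(f$diff_total)
  f
}

#' Pearson correlation between the minimum and Gini difference predictors
#'
#' @param features data.frame from [compute_features()].
#' @return Pearson correlation between `diff_min` and `diff_var`.
#' @export
feature_correlation <- function(features) {
  stopifnot(all(c("diff_min", "diff_var") %in% names(features)))
  if (nrow(features) < 3) stop("correlation needs at least 3 problems")
  if (stats::sd(features$diff_min) == 0 || stats::sd(features$diff_var) == 0) {
    stop("correlation is undefined for a constant predictor column")
  }
  stats::cor(features$diff_min, features$diff_var)
}
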