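#' Screen geometry anchors
#'
#' The three anchor points that define the analysis coordinate frame: the
#' start ("Next") button maps to (0, 0), the left option's check button to
#' (-1, 1) and the right option's to (1, 1). Defaults place them on a
#' 1920 x 1080 screen with pixel y growing downward; the anchor map absorbs
#' the flip, so no sign conventions are needed elsewhere.
#'
#' @param start,left,right pixel coordinates `c(x, y)` of the three anchors.
#' @return a list of class `screen_geometry`.
#' @export
make_geometry <- function(start = c(960, 1040),
                          left = c(310, 88),
                          right = c(1610, 88)) {
  g <- list(start = start, left = left, right = right)
  m <- rbind(c(start, 1), c(left, 1), c(right, 1))
  if (abs(det(m)) < 1e-8) {
    stop("degenerate screen geometry: the three anchor points are collinear")
  }
  g$px_to_an <- solve(m, rbind(c(0, 0), c(-1, 1), c(1, 1)))
  g$an_to_px <- solve(
    rbind(c(0, 0, 1), c(-1, 1, 1), c(1, 1, 1)),
    rbind(start, left, right)
  )
  class(g) <- "screen_geometry"
  g
}

apply_affine <- function(xy, coef) {
  xy <- matrix(xy, ncol = 2)
  cbind(xy, 1) %*% coef
}

#' Map pixel coordinates to the analysis frame
#'
#' Affine map determined by the three anchors: start -> (0, 0),
#' left target -> (-1, 1), right target -> (1, 1).
#'
#' @param xy_px matrix (or 2-vector) of pixel coordinates.
#' @param geometry a [make_geometry()] object.
#' @return matrix of analysis coordinates.
#' @export
to_analysis_coords <- function(xy_px, geometry = make_geometry()) {
  apply_affine(xy_px, geometry$px_to_an)
}

#' @rdname to_analysis_coords
#' @export
analysis_to_pixels <- function(xy_px, geometry = make_geometry()) {
  apply_affine(xy_px, geometry$an_to_px)
}

#' Orient x toward the non-Utilitarian option
#'
#' Negates x when the non-Utilitarian option was presented on the left, so
#' that across all trials positive x means movement toward the
#' non-Utilitarian option. Applying the function twice is the identity.
#'
#' @param x numeric vector of analysis-frame x positions.
#' @param side_of_non_utilitarian `"left"` or `"right"`.
#' @return x, sign-flipped if needed.
#' @export
invert_for_nonutilitarian <- function(x, side_of_non_utilitarian) {
  side <- match.arg(side_of_non_utilitarian, c("left", "right"))
  if (side == "left") -x else x
}

#' Time-normalize one trial onto equal time bins
#'
#' Linearly interpolates x and y against time and evaluates at `n_bins`
#' equally spaced times from the first to the last sample, so trials of
#' different durations become comparable. Bin 1 equals the first sample and
#' the last bin the last sample exactly.
#'
#' @param t_ms sample times (ms since trial onset), strictly increasing.
#' @param x,y coordinates at those times.
#' @param n_bins number of bins (101).
#' @return list with `x` and `y`, each of length `n_bins`.
#' @export
time_normalize <- function(t_ms, x, y, n_bins = 101) {
  if (length(t_ms) < 2) stop("time normalization needs at least 2 samples")
  if (any(diff(t_ms) <= 0)) stop("timestamps must be strictly increasing")
  stopifnot(length(x) == length(t_ms), length(y) == length(t_ms))
  tb <- seq(t_ms[1], t_ms[length(t_ms)], length.out = n_bins)
  out <- list(
    x = stats::approx(t_ms, x, xout = tb)$y,
    y = stats::approx(t_ms, y, xout = tb)$y
  )
  # endpoints are anchors of the interpolation; force exactness against
  # floating-point drift in the bin grid
  out$x[c(1, n_bins)] <- x[c(1, length(x))]
  out$y[c(1, n_bins)] <- y[c(1, length(y))]
  out
}

#' Preprocess raw trajectories into the analysis frame
#'
#' For every trial: map pixels to analysis coordinates, orient x toward the
#' non-Utilitarian option, and time-normalize to 101 equal bins. All trials
#' are retained; there is no exclusion rule.
#'
#' @param trajectories long data.frame (`participant_id`, `trial_index`,
#'   `t_ms`, `x_px`, `y_px`).
#' @param trials trial table with `side_of_non_utilitarian`, `choice`, `rt`.
#' @param geometry a [make_geometry()] object.
#' @param n_bins number of time bins (101).
#' @return long data.frame: `participant_id`, `trial_index`, `bin`, `x`,
#'   `y`, `choice`, `rt`.
#' @export
preprocess_trajectories <- function(trajectories, trials,
                                    geometry = make_geometry(), n_bins = 101) {
  key <- paste(trajectories$participant_id, trajectories$trial_index)
  tkey <- paste(trials$participant_id, trials$trial_index)
  groups <- split(seq_len(nrow(trajectories)), key)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    row <- match(key[idx[1]], tkey)
    if (is.na(row)) stop("trajectory without a matching trial: ", key[idx[1]])
    an <- to_analysis_coords(cbind(trajectories$x_px[idx], trajectories$y_px[idx]), geometry)
    x <- invert_for_nonutilitarian(an[, 1], trials$side_of_non_utilitarian[row])
    nz <- time_normalize(trajectories$t_ms[idx], x, an[, 2], n_bins)
    out[[g]] <- data.frame(
      participant_id = trials$participant_id[row],
      trial_index = trials$trial_index[row],
      bin = seq_len(n_bins), x = nz$x, y = nz$y,
      choice = trials$choice[row], rt = trials$rt[row],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean trajectory per choice group
#'
#' Per-bin mean and standard error of the oriented x position, separately
#' for Utilitarian and non-Utilitarian choices.
#'
#' @param normalized output of [preprocess_trajectories()].
#' @return data.frame with `choice`, `bin`, `mean_x`, `sem_x` (NA when a
#'   group holds a single trajectory) and `n`.
#' @export
mean_trajectories <- function(normalized) {
  groups <- split(normalized, normalized$choice)
  groups <- Filter(function(d) nrow(d) > 0, groups)
  if (length(groups) == 0) {
    warning("no trajectories to average")
    return(data.frame())
  }
  res <- do.call(rbind, lapply(groups, function(d) {
    n_traj <- length(unique(paste(d$participant_id, d$trial_index)))
    agg <- stats::aggregate(x ~ bin, data = d, FUN = mean)
    sdv <- stats::aggregate(x ~ bin, data = d, FUN = stats::sd)
    data.frame(
      choice = d$choice[1], bin = agg$bin, mean_x = agg$x,
      sem_x = if (n_traj > 1) sdv$x / sqrt(n_traj) else NA_real_,
      n = n_traj, stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  res
}
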