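test_that("the affine anchor map sends anchors to their coded coordinates", {
  g <- make_geometry(start = c(960, 1040), left = c(310, 88), right = c(1610, 88))
  expect_equal(as.vector(to_analysis_coords(c(960, 1040), g)), c(0, 0))
  expect_equal(as.vector(to_analysis_coords(c(310, 88), g)), c(-1, 1))
  expect_equal(as.vector(to_analysis_coords(c(1610, 88), g)), c(1, 1))
  # midpoint of the two targets maps to (0, 1)
  expect_equal(as.vector(to_analysis_coords(c(960, 88), g)), c(0, 1))
  # the pixel map inverts it
  xy <- matrix(c(500, 300, 1200, 700), 2, byrow = TRUE)
  expect_equal(analysis_to_pixels(to_analysis_coords(xy, g), g), xy,
               tolerance = 1e-9)
})

test_that("collinear anchors are rejected", {
  expect_error(make_geometry(c(0, 0), c(1, 1), c(2, 2)), "collinear")
})

test_that("x inversion orients toward the non-Utilitarian option", {
  x <- c(-0.8, 0, 0.3)
  expect_equal(invert_for_nonutilitarian(x, "right"), x)
  expect_equal(invert_for_nonutilitarian(x, "left"), -x)
  expect_equal(
    invert_for_nonutilitarian(invert_for_nonutilitarian(x, "left"), "left"), x
  )
})

test_that("time normalization interpolates onto 101 equal bins", {
  # two samples: a pure linear ramp
  nz <- time_normalize(c(0, 1000), x = c(0, 1), y = c(0, 1))
  expect_length(nz$x, 101)
  expect_equal(nz$x, seq(0, 1, length.out = 101), tolerance = 1e-12)
  expect_equal(nz$y, seq(0, 1, length.out = 101), tolerance = 1e-12)
  # already uniform 101 samples: a fixed point
  set.seed(4)
  x <- cumsum(rnorm(101))
  y <- seq(0, 1, length.out = 101)
  nz <- time_normalize(seq(0, 2000, length.out = 101), x, y)
  expect_equal(nz$x, x, tolerance = 1e-12)
  expect_equal(nz$y, y, tolerance = 1e-12)
  # 60 Hz samples of a 1.97 s trial: endpoints preserved exactly
  t_ms <- seq(0, 1970, by = 1000 / 60)
  t_ms <- c(t_ms, 1970)
  xr <- cumsum(rnorm(length(t_ms), 0, 0.05))
  nz <- time_normalize(t_ms, xr, seq_along(t_ms) / length(t_ms))
  expect_length(nz$x, 101)
  expect_identical(nz$x[1], xr[1])
  expect_identical(nz$x[101], xr[length(xr)])
  # linear interpolation cannot overshoot the input range
  expect_gte(min(nz$x), min(xr))
  expect_lte(max(nz$x), max(xr))
})

test_that("time normalization is translation-equivariant in x", {
  set.seed(9)
  t_ms <- sort(runif(40, 0, 1500))
  t_ms[1] <- 0
  x <- cumsum(rnorm(40))
  y <- seq(0, 1, length.out = 40)
  a <- time_normalize(t_ms, x, y)
  b <- time_normalize(t_ms, x + 2.5, y)
  expect_equal(b$x, a$x + 2.5, tolerance = 1e-12)
})

test_that("degenerate sample sequences are rejected", {
  expect_error(time_normalize(c(0), 1, 1), "at least 2")
  expect_error(time_normalize(c(0, 10, 10), c(1, 2, 3), c(1, 2, 3)),
               "strictly increasing")
})

test_that("preprocessing recovers exact endpoints for every trial", {
  e <- small_experiment()
  nz <- preprocess_trajectories(e$trajectories, e$trials, e$config$geometry)
  expect_equal(nrow(nz), nrow(e$trials) * 101)
  first <- nz[nz$bin == 1, ]
  last <- nz[nz$bin == 101, ]
  expect_true(all(abs(first$x) < 1e-9 & abs(first$y) < 1e-9))
  expect_true(all(abs(last$y - 1) < 1e-9))
  expect_true(all(abs(last$x - ifelse(last$choice == "N", 1, -1)) < 1e-9))
})

test_that("mean trajectories aggregate correctly", {
  one <- data.frame(
    participant_id = "s01", trial_index = 1, bin = 1:101,
    x = seq(0, 1, length.out = 101), y = seq(0, 1, length.out = 101),
    choice = "N", rt = 2
  )
  m <- mean_trajectories(one)
  expect_equal(m$mean_x, one$x)
  expect_true(all(is.na(m$sem_x)))
  # two mirror-image trajectories average to zero
  two <- rbind(one, transform(one, trial_index = 2, x = -x))
  m2 <- mean_trajectories(two)
  expect_true(all(abs(m2$mean_x) < 1e-12))
  expect_true(all(m2$n == 2))
})

test_that("mean-trajectory plots are built from the summaries", {
  e <- small_experiment()
  nz <- preprocess_trajectories(e$trajectories, e$trials, e$config$geometry)
  p <- plot_mean_trajectories(mean_trajectories(nz))
  expect_s3_class(p, "ggplot")
})
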