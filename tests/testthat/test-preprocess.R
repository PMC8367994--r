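test_that("smoother restores a constant signal through a gap exactly", {
  t <- seq(0, 0.99, by = 0.01)
  valid <- rep(TRUE, 100); valid[40:44] <- FALSE
  pos <- cbind(rep(5, 100), rep(-3, 100))
  pos[!valid, ] <- NA
  tr <- sensor_trajectory("TT", t, pos, valid)
  sm <- dct_smooth(tr, smoother_config())
  expect_true(all(sm$valid))
  expect_equal(sm$positions[, 1], rep(5, 100), tolerance = 1e-9)
  expect_equal(sm$positions[, 2], rep(-3, 100), tolerance = 1e-9)
  expect_identical(sm$times, tr$times)
})

test_that("zero penalty on a complete signal is the identity", {
  t <- seq(0, 0.5, by = 0.01)
  pos <- cbind(sin(2 * pi * t) * 4, cos(2 * pi * t) * 2)
  tr <- sensor_trajectory("TB", t, pos)
  sm <- dct_smooth(tr, smoother_config(lambda = 0))
  expect_equal(sm$positions, tr$positions, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("GCV smoothing reduces error against the known clean signal", {
  withr::local_seed(11)
  t <- seq(0, 1.27, by = 0.01)
  clean <- sin(2 * pi * t)          # 1 Hz component, well below Nyquist
  noisy <- clean + rnorm(length(t), sd = 0.5)
  tr <- sensor_trajectory("TT", t, cbind(noisy, noisy))
  sm <- dct_smooth(tr, smoother_config())
  rmse_raw <- sqrt(mean((noisy - clean)^2))
  rmse_sm <- sqrt(mean((sm$positions[, 1] - clean)^2))
  expect_lt(rmse_sm, rmse_raw)
})

test_that("smoother is linear in its input at fixed penalty", {
  withr::local_seed(3)
  t <- seq(0, 0.63, by = 0.01)
  x <- rnorm(length(t)); z <- rnorm(length(t))
  smooth1 <- function(v) {
    tr <- sensor_trajectory("TT", t, cbind(v, v))
    dct_smooth(tr, smoother_config(lambda = 5))$positions[, 1]
  }
  lhs <- smooth1(2.5 * x - 1.5 * z)
  rhs <- 2.5 * smooth1(x) - 1.5 * smooth1(z)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("smoother preconditions are enforced with informative errors", {
  t <- seq(0, 0.99, by = 0.01)
  pos <- cbind(t, t)
  v_few <- c(rep(TRUE, 8), rep(FALSE, 92))
  pos_few <- pos; pos_few[!v_few, ] <- NA
  expect_error(dct_smooth(sensor_trajectory("TT", t, pos_few, v_few)),
               "valid samples")
  v_gap <- rep(TRUE, 100); v_gap[30:60] <- FALSE
  pos_gap <- pos; pos_gap[!v_gap, ] <- NA
  expect_error(dct_smooth(sensor_trajectory("TT", t, pos_gap, v_gap),
                          smoother_config(max_gap = 20)),
               "max_gap")
})

test_that("occlusal transform recovers constructed geometry", {
  # already on y = 0, anterior at +x -> identity
  t0 <- estimate_occlusal_transform(rbind(c(10, 0), c(-10, 0)))
  expect_equal(t0$rotation, 0, tolerance = 1e-9)
  expect_equal(t0$translation, c(0, 0), tolerance = 1e-9)

  # line rotated +30 degrees about the origin -> -30 degrees recovered
  phi <- 30 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  bp <- t(R %*% t(rbind(c(10, 0), c(2, 0), c(-10, 0))))
  t1 <- estimate_occlusal_transform(bp)
  expect_equal(t1$rotation, -phi, tolerance = 1e-9)
  moved <- apply_transform(t1, bp)
  expect_equal(moved[, 2], rep(0, 3), tolerance = 1e-9)
  expect_gt(moved[1, 1], 0)         # anterior point faces forward
  expect_lt(attr(t1, "residual"), 1e-9)

  expect_error(estimate_occlusal_transform(rbind(c(1, 1), c(1, 1))),
               "degenerate")
})

test_that("rigid transforms are isometries with exact inverses", {
  withr::local_seed(5)
  for (i in 1:20) {
    tf <- rigid_transform2d(runif(1, -pi, pi), rnorm(2, sd = 10))
    X <- matrix(rnorm(20), ncol = 2)
    Y <- apply_transform(tf, X)
    expect_equal(as.vector(dist(Y)), as.vector(dist(X)), tolerance = 1e-9)
    back <- apply_transform(transform_invert(tf), Y)
    expect_equal(back, X, tolerance = 1e-9)
  }
  # composition applies left-to-right
  a <- rigid_transform2d(0.3, c(1, 2)); b <- rigid_transform2d(-0.8, c(-4, 0))
  X <- matrix(rnorm(10), ncol = 2)
  expect_equal(apply_transform(transform_compose(a, b), X),
               apply_transform(b, apply_transform(a, X)), tolerance = 1e-9)
})

test_that("translating a recording shifts every position and nothing else", {
  rec <- make_test_recording()
  tf <- rigid_transform2d(0, c(5, -3))
  out <- apply_transform(tf, rec)
  expect_equal(out$trajectories$TT$positions,
               rec$trajectories$TT$positions +
                 matrix(c(5, -3), nrow = length(rec$trajectories$TT$times),
                        ncol = 2, byrow = TRUE), tolerance = 1e-12)
  expect_identical(unlist(out$landmarks), unlist(rec$landmarks))
})

test_that("palate trace tracks the upper envelope and trims outliers", {
  # samples on a parabola y = -x^2/20 + 20 with sub-envelope scatter
  withr::local_seed(9)
  x <- runif(3000, -15, 15)
  y <- -x^2 / 20 + 20 - runif(3000, 0, 0.3)
  t <- seq(0, by = 0.01, length.out = 3000)
  tr <- sensor_trajectory("TT", t, cbind(x, y))
  tb <- sensor_trajectory("TB", t, cbind(x, y - 1))
  rec <- token_recording("P01", 1, 1, 5, list(TT = tr, TB = tb),
                         landmark_set(1, 10, 20, 29))
  trace <- estimate_palate(rec, bin_mm = 1)
  expect_equal(trace$y_mm, -trace$x_mm^2 / 20 + 20, tolerance = 0.4)

  # one extreme outlier is trimmed by the MAD rule
  y2 <- y; y2[1] <- 100
  rec2 <- token_recording("P01", 1, 1, 5,
                          list(TT = sensor_trajectory("TT", t, cbind(x, y2)),
                               TB = tb),
                          landmark_set(1, 10, 20, 29))
  trace2 <- estimate_palate(rec2, bin_mm = 1)
  expect_lt(max(trace2$y_mm), 30)

  # single sample per bin -> trace equals the samples
  xs <- c(0.5, 1.5, 2.5); ys <- c(1, 2, 3)
  rec3 <- token_recording(
    "P01", 1, 1, 5,
    list(TT = sensor_trajectory("TT", c(0, 0.01, 0.02), cbind(xs, ys)),
         TB = sensor_trajectory("TB", c(0, 0.01, 0.02), cbind(xs, ys))),
    landmark_set(0.001, 0.005, 0.01, 0.019))
  trace3 <- estimate_palate(rec3, bin_mm = 1, sensors = "TT")
  expect_equal(trace3$y_mm, ys)
  expect_equal(trace3$n, rep(1L, 3))
})
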