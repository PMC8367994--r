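test_that("signed turning angles carry orientation and match the unsigned sum", {
  straight <- cbind(0:30, rep(0, 31))
  expect_equal(signed_step_angles(straight)$angle, rep(0, 29))

  # consistent counter-clockwise arc -> all positive angles
  phi <- seq(0, pi, length.out = 31)
  arc <- cbind(cos(-phi), sin(-phi) + 1)  # traversed counter-clockwise
  expect_true(all(signed_step_angles(arc[31:1, ])$angle > 0))

  withr::local_seed(37)
  for (i in 1:20) {
    p <- random_path()
    sa <- signed_step_angles(p)
    expect_true(all(sa$angle > -pi - 1e-12 & sa$angle <= pi + 1e-12))
    expect_equal(sum(abs(sa$angle)), path_angular_displacement(p),
                 tolerance = 1e-9)
  }

  # zero-length step is flagged and contributes angle 0
  stutter <- cbind(c(0, 1, 1, 2:29), rep(0, 31))
  sa <- signed_step_angles(stutter)
  expect_true(any(sa$degenerate))
  expect_equal(sa$angle[sa$degenerate], rep(0, sum(sa$degenerate)))
})

test_that("points of return delimit monotone periods with the plateau rule", {
  mono <- points_of_return(1:7)
  expect_length(mono$k_indices, 0L)
  expect_equal(mono$l, 1L)

  alt <- points_of_return(c(0, 1, 0, 1, 0, 1, 0))
  expect_length(alt$k_indices, 5L)
  expect_equal(alt$l, 6L)

  expect_equal(points_of_return(rep(2, 7))$l, 1L)

  # interior plateau continues the previous direction: no spurious return
  expect_equal(points_of_return(c(1, 2, 2, 3, 4, 5, 6))$l, 1L)
  # leading plateau takes the first nonzero direction
  expect_equal(points_of_return(c(2, 2, 3, 4, 5, 6, 7))$l, 1L)
  # plateau then reversal is a single return
  expect_equal(points_of_return(c(1, 2, 2, 1, 0, -1, -2))$l, 2L)
})

test_that("F hits its analytic values on the canonical constructions", {
  expect_equal(fluctuation_F(rep(0.3, 7)), 0)
  # maximal alternation between scale bounds on the uniform grid -> 1
  expect_equal(fluctuation_F(rep(c(-pi, pi), length.out = 7)), 1,
               tolerance = 1e-15)
  # monotone ramp across the scale: single period, (s/6)/(6s) = 1/36
  expect_equal(fluctuation_F(seq(-pi, pi, length.out = 7)), 1 / 36,
               tolerance = 1e-12)
  expect_error(fluctuation_F(rep(0, 7), n = c(1, 2, 2, 3, 4, 5, 6)),
               "strictly increasing")
  expect_error(fluctuation_F(c(0, 4, 0, 0, 0, 0, 0)), "outside the scale")
})

test_that("F is invariant to affine changes of the window time axis", {
  withr::local_seed(41)
  for (i in 1:50) {
    x <- runif(7, -pi, pi)
    n <- cumsum(runif(7, 0.2, 2))
    f0 <- fluctuation_F(x, n)
    a <- runif(1, 0.1, 10); b <- rnorm(1, sd = 5)
    expect_equal(fluctuation_F(x, a * n + b), f0, tolerance = 1e-9)
  }
})

test_that("an added direction reversal never decreases F", {
  # monotone ramp vs the same ramp with an interior reversal notch
  ramp <- seq(-pi, pi, length.out = 7)
  notched <- ramp; notched[4] <- ramp[3] - 0.5
  expect_gt(fluctuation_F(notched), fluctuation_F(ramp))
  # deepening the notch increases F further
  deeper <- ramp; deeper[4] <- ramp[3] - 1.5
  expect_gt(fluctuation_F(deeper), fluctuation_F(notched))
})

test_that("sliding windows tile the angle series with stride one", {
  theta <- rep(0, 29)
  out <- sliding_fluctuation(theta)
  expect_equal(nrow(out), 23L)
  expect_equal(out$F, rep(0, 23))
  expect_error(sliding_fluctuation(rep(0, 6)), "at least 7")

  # uniform grid: every window equals a direct evaluation on integer indices
  withr::local_seed(43)
  theta <- runif(29, -pi, pi)
  out <- sliding_fluctuation(theta, times = seq(0.1, by = 0.02,
                                                length.out = 29))
  direct <- vapply(1:23, function(i) fluctuation_F(theta[i:(i + 6)]),
                   numeric(1))
  expect_equal(out$F, direct, tolerance = 1e-12)
})

test_that("tongue-front fluctuation averages the sensor series", {
  expect_equal(tongue_front_fluctuation(c(0, 0.4), c(1, 0.4)), c(0.5, 0.4))
  expect_error(tongue_front_fluctuation(1:3 / 10, 1:2 / 10), "lengths differ")
  withr::local_seed(47)
  a <- runif(23); b <- runif(23)
  fr <- tongue_front_fluctuation(a, b)
  expect_true(all(fr >= pmin(a, b) & fr <= pmax(a, b)))
})

test_that("token fluctuation spans 23 slices within [0, 1]", {
  coh <- tiny_cohort(seed = 51, n_participants = 1, n_token_types = 1,
                     n_blocks = 1)
  pre <- lapply(coh$recordings, preprocess_recording,
                sensors = c("TT", "TB"))
  fl <- fluctuation_table(lapply(pre, resample_token))
  expect_equal(sort(unique(fl$fts_index)), 1:23)
  expect_true(all(fl$F_TT >= 0 & fl$F_TT <= 1))
  expect_true(all(fl$F_front >= 0 & fl$F_front <= 1))
  expect_equal(fl$F_front, (fl$F_TT + fl$F_TB) / 2, tolerance = 1e-12)
})
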