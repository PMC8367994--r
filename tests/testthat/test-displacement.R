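test_that("path distance sums inter-slice step lengths", {
  collinear <- cbind(0:30, rep(0, 31))
  expect_equal(path_distance(collinear), 30)
  expect_equal(path_distance(matrix(2, 31, 2)), 0)
  expect_error(path_distance(matrix(0, 30, 2)), "31")

  withr::local_seed(13)
  for (i in 1:25) {
    p <- random_path()
    acc <- 0
    for (j in 1:30) acc <- acc + sqrt(sum((p[j + 1, ] - p[j, ])^2))
    expect_equal(path_distance(p), acc, tolerance = 1e-9)
  }
})

test_that("angular displacement sums unsigned turning angles in [0, pi]", {
  expect_equal(path_angular_displacement(cbind(0:30, rep(0, 31))), 0)

  # strict alternation: every consecutive vector pair reverses -> 29 * pi
  zig <- cbind(rep(c(0, 1), length.out = 31), rep(0, 31))
  expect_equal(path_angular_displacement(zig), 29 * pi, tolerance = 1e-9)

  # one right-angle turn, otherwise straight
  bend <- rbind(cbind(0:15, 0), cbind(15, 1:15))
  expect_equal(path_angular_displacement(bend), pi / 2, tolerance = 1e-9)

  withr::local_seed(17)
  for (i in 1:25) {
    p <- random_path()
    expect_equal(path_angular_displacement(p), brute_theta(p),
                 tolerance = 1e-9)
    ang <- abs(signed_step_angles(p)$angle)
    expect_true(all(ang >= 0 & ang <= pi + 1e-12))
  }
})

test_that("path metrics are rigid-invariant; scaling moves D only", {
  withr::local_seed(23)
  for (i in 1:10) {
    p <- random_path()
    tf <- rigid_transform2d(runif(1, -pi, pi), rnorm(2, sd = 20))
    q <- apply_transform(tf, p)
    expect_equal(path_distance(q), path_distance(p), tolerance = 1e-9)
    expect_equal(path_angular_displacement(q), path_angular_displacement(p),
                 tolerance = 1e-9)
    k <- runif(1, 0.2, 5)
    expect_equal(path_distance(p * k), k * path_distance(p),
                 tolerance = 1e-9)
    expect_equal(path_angular_displacement(p * k),
                 path_angular_displacement(p), tolerance = 1e-9)
  }
})

test_that("pooled z-scores have the standard properties", {
  p <- zscore_fit(c(1, 2, 3))
  expect_equal(zscore_apply(p, c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zscore_apply(p, p$mu), 0)
  expect_error(zscore_fit(rep(4, 10)), "degenerate")

  withr::local_seed(29)
  draws <- rnorm(1e5)
  pf <- zscore_fit(draws)
  expect_lt(abs(pf$mu), 0.02)
  expect_lt(abs(pf$sigma - 1), 0.02)
})

test_that("tongue-front displacement is the double z-score of Eq-style sums", {
  coh <- tiny_cohort(seed = 31, n_participants = 2, n_token_types = 2,
                     n_blocks = 2, noise_sd = 0, dropout_prob = 0)
  pt <- lapply(coh$recordings, resample_token)
  met <- path_metrics(pt)
  tf <- tongue_front_displacement(met)
  # z-score property over the pool
  expect_lt(abs(mean(tf$T)), 1e-9)
  expect_lt(abs(sd(tf$T) - 1), 1e-9)
  # T is the outer z-score of the four-component sum
  expect_equal(tf$T, as.vector(scale(tf$sum_z)), tolerance = 1e-9)
  expect_equal(tf$sum_z, tf$z_D_TT + tf$z_Theta_TT + tf$z_D_TB + tf$z_Theta_TB,
               tolerance = 1e-9)
})

test_that("a two-token pool yields T = (-0.7071, +0.7071)", {
  # closed form for n = 2 with the sample (n-1) standard deviation
  pts <- list()
  t <- seq(0, 0.8, by = 0.01)
  for (r in c(3L, 7L)) {
    amp <- if (r == 3L) 6 else 3
    rec <- token_recording(
      "P01", 1, 1, r,
      list(TT = sensor_trajectory("TT", t, cbind(20 * t, amp * sin(4 * pi * t))),
           TB = sensor_trajectory("TB", t, cbind(15 * t, amp * cos(4 * pi * t)))),
      landmark_set(0.1, 0.3, 0.5, 0.7))
    pts[[as.character(r)]] <- resample_token(rec)
  }
  tf <- tongue_front_displacement(path_metrics(pts))
  expect_equal(sort(tf$T), c(-1, 1) / sqrt(2), tolerance = 1e-6)
})

test_that("degenerate pools and missing components are rejected", {
  t <- seq(0, 0.8, by = 0.01)
  rec <- function(r, b) token_recording(
    "P01", 1, b, r,
    list(TT = sensor_trajectory("TT", t, cbind(10 * t, sin(2 * pi * t))),
         TB = sensor_trajectory("TB", t, cbind(8 * t, cos(2 * pi * t)))),
    landmark_set(0.1, 0.3, 0.5, 0.7))
  identical_tokens <- lapply(1:3, function(b) resample_token(rec(5L, b)))
  expect_error(tongue_front_displacement(path_metrics(identical_tokens)),
               "degenerate")

  met <- path_metrics(identical_tokens)
  expect_error(tongue_front_displacement(met[met$sensor == "TT", ]),
               "TB")
})

test_that("displacement range is the rate-3 minus rate-7 mean contrast", {
  tab <- data.frame(
    participant = "P01", token_type = 1L,
    block = rep(1:2, 3), rate = c(3, 3, 5, 5, 7, 7),
    sensor_set = "tongue_front",
    T = c(1.0, 1.4, 0.2, 0.0, -0.7, -0.9))
  rg <- displacement_range(tab)
  expect_equal(rg$range_value, 1.2 - (-0.8))
  expect_false(rg$absent)

  # identical motion at both extremes -> range 0
  tab$T <- 0.5
  expect_equal(displacement_range(tab)$range_value, 0)

  # missing rate-7 cell -> absent, not imputed
  tab2 <- tab[tab$rate != 7, ]
  rg2 <- displacement_range(tab2)
  expect_true(rg2$absent)
  expect_true(is.na(rg2$range_value))
})
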