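# Frames for the model tests are built directly so each modelling stage is
# exercised in isolation from the kinematic pipeline.

make_duration_frame <- function(n_participants = 5, n_token_types = 4,
                                interaction = -0.03, noise_sd = 0.01,
                                seed = 1) {
  withr::with_seed(seed, {
    ranges <- runif(n_participants * n_token_types, 0.5, 4)
    g <- expand.grid(p = seq_len(n_participants),
                     tt = seq_len(n_token_types), rate = 3:7)
    g$range <- ranges[(g$p - 1) * n_token_types + g$tt]
    g$dur <- 0.9 + 0.05 * g$range + (g$rate - 3) *
      (-0.04 + interaction * g$range) + rnorm(nrow(g), 0, noise_sd)
    data.frame(Duration = g$dur, DisplacementRange = g$range,
               Rate = factor(g$rate, levels = 3:7),
               Participant = factor(paste0("P", g$p)),
               TokenType = factor(g$tt))
  })
}

test_that("duration GLMM recovers programmed effects and reports r2m <= r2c", {
  fr <- make_duration_frame(interaction = -0.03, seed = 2)
  fit <- fit_duration_glmm(fr)
  cf <- fit$coefficients
  ia <- cf[grep(":", rownames(cf)), "Estimate"]
  expect_length(ia, 4L)
  expect_true(all(ia < 0))
  expect_gt(cf["DisplacementRange", "Estimate"], 0)
  expect_lte(fit$r2m, fit$r2c)
  expect_true(all(c("Estimate", "Std. Error", "df", "t value", "p value")
                  %in% names(cf)))
})

test_that("GLMM estimates are invariant to row order", {
  fr <- make_duration_frame(seed = 3)
  fit1 <- fit_duration_glmm(fr)
  withr::with_seed(4, fr2 <- fr[sample(nrow(fr)), ])
  fit2 <- fit_duration_glmm(fr2)
  expect_equal(fit1$coefficients$Estimate, fit2$coefficients$Estimate,
               tolerance = 1e-6)
  expect_equal(fit1$r2m, fit2$r2m, tolerance = 1e-6)
})

test_that("GLMM preconditions reject degenerate designs", {
  fr <- make_duration_frame(seed = 5)
  single <- droplevels(fr[fr$Participant == "P1", ])
  expect_error(fit_duration_glmm(single), "single participant")
  flat <- fr; flat$DisplacementRange <- 1
  expect_error(fit_duration_glmm(flat), "vary")
})

test_that("model comparison identifies the variant carrying the signal", {
  base <- make_duration_frame(seed = 6, noise_sd = 0.005)
  # durations were built from base$DisplacementRange; competitors get
  # scrambled copies of the predictor
  scramble <- function(f, seed) {
    withr::with_seed(seed, {
      u <- unique(f$DisplacementRange)
      f$DisplacementRange <- sample(u)[match(f$DisplacementRange, u)]
    })
    f
  }
  frames <- list(tongue_front = base,
                 tip = scramble(base, 7),
                 whole_tongue = scramble(base, 8),
                 whole_tract = scramble(base, 9))
  cmp <- compare_displacement_models(frames)
  expect_identical(attr(cmp, "winner"), "tongue_front")
  # the symmetric construct: signal planted in whole_tract instead
  frames2 <- frames[c("tip", "whole_tongue")]
  frames2$whole_tract <- base
  frames2$tongue_front <- scramble(base, 10)
  cmp2 <- compare_displacement_models(frames2)
  expect_identical(attr(cmp2, "winner"), "whole_tract")
})

test_that("model comparison flags ties and misaligned responses", {
  base <- make_duration_frame(seed = 11)
  cmp <- compare_displacement_models(list(a = base, b = base))
  expect_true(attr(cmp, "tied"))
  shifted <- base
  shifted$Duration <- shifted$Duration + 0.01
  expect_error(compare_displacement_models(list(a = base, b = shifted)),
               "response rows differ")
})

make_fluct_frame <- function(n_participants = 4, n_tokens_per = 10,
                             pattern = c("banded", "noise"), rho = 0,
                             seed = 1) {
  pattern <- match.arg(pattern)
  withr::with_seed(seed, {
    rows <- list()
    for (p in seq_len(n_participants)) {
      tfd <- (p - (n_participants + 1) / 2) / (n_participants / 3)
      for (tok in seq_len(n_tokens_per)) {
        fts <- 1:23
        mu <- if (pattern == "banded") {
          0.08 + 0.03 * abs(tfd) * cos(pi * (fts - 1) / 22) *
            sign(abs(tfd) - 0.6)
        } else rep(0.08, 23)
        e <- rnorm(23, 0, 0.02)
        if (rho > 0) e <- as.vector(stats::filter(e, rho,
                                                  method = "recursive"))
        rows[[length(rows) + 1]] <- data.frame(
          Fluctuation = mu + e, FTS = fts, TFd = tfd,
          SPS = 3 + (tok %% 5), TokenType = factor(1 + tok %% 2),
          Participant = factor(paste0("P", p)),
          series_start = fts == 1)
      }
    }
    do.call(rbind, rows)
  })
}

test_that("GAMM validates its frame", {
  fr <- make_fluct_frame(seed = 21)
  bad <- fr; bad$series_start <- FALSE
  expect_error(fit_fluctuation_gamm(bad), "series_start")
  bad2 <- fr; bad2$Fluctuation[5] <- NaN
  expect_error(fit_fluctuation_gamm(bad2), "non-finite")
})

test_that("white-noise fluctuation yields a near-null smooth", {
  fr <- make_fluct_frame(pattern = "noise", seed = 22)
  fit <- fit_fluctuation_gamm(fr, k_te = c(5, 4), k_fs = 4)
  expect_lt(fit$dev_expl, 0.10)
})

test_that("AR(1) correction shrinks residual autocorrelation", {
  fr <- make_fluct_frame(pattern = "banded", rho = 0.6, seed = 23)
  fit <- fit_fluctuation_gamm(fr, k_te = c(5, 4), k_fs = 4)
  expect_gt(fit$acf_uncorrected, 0.2)
  expect_lt(abs(fit$acf_corrected), abs(fit$acf_uncorrected))
})

test_that("the fitted surface recovers a programmed banded pattern", {
  fr <- make_fluct_frame(pattern = "banded", n_participants = 6,
                         n_tokens_per = 12, seed = 24)
  fit <- fit_fluctuation_gamm(fr)
  expect_lte(fit$r2_adj, 1)
  surf <- predict_fluctuation_surface(fit)
  contrast <- function(tfd_val) {
    tv <- sort(unique(surf$TFd))
    s <- surf[surf$TFd == tv[which.min(abs(tv - tfd_val))], ]
    mean(s$F_hat[s$FTS <= 7]) - mean(s$F_hat[s$FTS >= 17])
  }
  # programmed: early effort at |TFd| extremes, late effort mid-band
  expect_gt(contrast(min(fr$TFd)), 0)
  expect_gt(contrast(max(fr$TFd)), 0)
  expect_lt(contrast(0), 0)
})
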