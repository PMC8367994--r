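## stats_models: the duration GLMM (displacement range x reiterant rate with
## by-participant random intercepts and displacement-range slopes), the
## four-variant model comparison, and the fluctuation GAMM (tensor-product
## smooth over fluctuation time slice x scaled tongue-front displacement
## range, factor-smooth and random-effect smooths for participant, with a
## two-pass AR(1) residual correction).

#' Build the duration model frame
#'
#' Joins per-token durations with the per participant x token-type
#' displacement range of one sensor-set variant. Duration is modelled in
#' seconds; reiterant rate enters as a treatment-coded factor with
#' 3 syllables/s as reference. By default rows are cell means per
#' participant x token type x rate (the aggregation implied by the study's
#' reported degrees of freedom); `aggregate = "token"` keeps one row per
#' token.
#'
#' @param t_table Per-token displacement table carrying `participant`,
#'   `token_type`, `block`, `rate`, `duration` (from
#'   [tongue_front_displacement()] or [displacement_summary()]).
#' @param ranges Output of [displacement_range()].
#' @param sensor_set Variant to use from `ranges`; default `"tongue_front"`.
#' @param aggregate `"cell_mean"` (default) or `"token"`.
#' @return Data frame with `Duration`, `DisplacementRange`, `Rate` (factor,
#'   reference "3"), `Participant`, `TokenType`.
#' @export
duration_model_frame <- function(t_table, ranges,
                                 sensor_set = "tongue_front",
                                 aggregate = c("cell_mean", "token")) {
  aggregate <- match.arg(aggregate)
  rg <- ranges[ranges$sensor_set == sensor_set & !ranges$absent, ]
  if (!nrow(rg)) .stop_data("no ranges available for sensor set '",
                            sensor_set, "'")
  tt <- t_table
  if (!is.null(tt$sensor_set)) tt <- tt[tt$sensor_set == sensor_set, ]
  if (aggregate == "cell_mean") {
    tt <- stats::aggregate(duration ~ participant + token_type + rate,
                           data = tt, FUN = mean)
  }
  key_t <- paste(tt$participant, tt$token_type, sep = ".")
  key_r <- paste(rg$participant, rg$token_type, sep = ".")
  idx <- match(key_t, key_r)
  tt$DisplacementRange <- rg$range_value[idx]
  tt <- tt[!is.na(tt$DisplacementRange), ]
  if (!nrow(tt)) .stop_data("no rows with a displacement range; ",
                            "check rate-3 and rate-7 coverage")
  data.frame(Duration = tt$duration,
             DisplacementRange = tt$DisplacementRange,
             Rate = factor(as.character(tt$rate),
                           levels = c("3", "4", "5", "6", "7")),
             Participant = factor(tt$participant),
             TokenType = factor(tt$token_type),
             stringsAsFactors = FALSE)
}

## marginal / conditional r2 by variance partition: fixed-effect variance is
## the variance of X beta over the data; random-effect variance is the mean
## diagonal of Z G Z' (computed via the relative covariance factor Lambda).
.r2_mixed <- function(fit) {
  X <- lme4::getME(fit, "X")
  var_f <- stats::var(as.vector(X %*% lme4::fixef(fit)))
  Z <- lme4::getME(fit, "Z")
  Lam <- lme4::getME(fit, "Lambda")
  sig2 <- stats::sigma(fit)^2
  ZL <- Z %*% Lam
  var_r <- sig2 * mean(Matrix::rowSums(ZL^2))
  tot <- var_f + var_r + sig2
  c(r2m = var_f / tot, r2c = (var_f + var_r) / tot)
}

#' Fit the duration GLMM
#'
#' `Duration ~ DisplacementRange * Rate + (1 + DisplacementRange |
#' Participant)`, treatment coding with the 3 syllables/s prompt as
#' reference, fitted by REML with Satterthwaite degrees of freedom for the
#' coefficient tests. A singular random-effects fit is recorded as a note,
#' not an error.
#'
#' @param frame Data frame from [duration_model_frame()].
#' @return An object of class `duration_glmm`: list with the fitted model
#'   (`fit`), the coefficient table (`coefficients`: Estimate, Std. Error,
#'   df, t value, p value), `r2m`, `r2c`, `singular` and `note`.
#' @export
fit_duration_glmm <- function(frame) {
  need <- c("Duration", "DisplacementRange", "Rate", "Participant")
  if (!all(need %in% names(frame)))
    .stop_data("frame must carry ", paste(need, collapse = ", "))
  if (anyNA(frame[need])) .stop_data("missing values in fixed-effect columns")
  if (nlevels(droplevels(frame$Participant)) < 2L)
    .stop_data("random effects inestimable with a single participant")
  if (stats::var(frame$DisplacementRange) == 0 ||
      length(unique(frame$Rate)) < 2L)
    .stop_data("both interaction factors must vary")
  fit <- lmerTest::lmer(
    Duration ~ DisplacementRange * Rate + (1 + DisplacementRange | Participant),
    data = frame, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  cf <- as.data.frame(summary(fit)$coefficients)
  names(cf) <- c("Estimate", "Std. Error", "df", "t value", "p value")
  r2 <- .r2_mixed(fit)
  structure(list(fit = fit, coefficients = cf,
                 r2m = unname(r2["r2m"]), r2c = unname(r2["r2c"]),
                 singular = singular,
                 note = if (singular) "singular random-effects fit" else NULL),
            class = "duration_glmm")
}

#' @export
print.duration_glmm <- function(x, ...) {
  cat("Duration GLMM: Duration ~ DisplacementRange * Rate +",
      "(1 + DisplacementRange | Participant)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("r2 (marginal) = %.3f, r2 (conditional) = %.3f\n", x$r2m, x$r2c))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Compare the four displacement-range model variants
#'
#' Refits the duration model by maximum likelihood on each variant's frame
#' and ranks the variants by information criteria. All frames must model
#' the identical response rows. The variants share a model structure (only
#' the displacement-range predictor differs), so AIC/BIC/log-likelihood
#' order them directly.
#'
#' @param frames Named list of frames from [duration_model_frame()], one per
#'   sensor-set variant.
#' @return Data frame with `sensor_set`, `df`, `AIC`, `BIC`, `logLik`,
#'   `dAIC`, `best`; the winning variant name is attached as attribute
#'   `winner` (with ties flagged in attribute `tied`).
#' @export
compare_displacement_models <- function(frames) {
  if (length(frames) < 2L || is.null(names(frames)))
    .stop_data("frames must be a named list of >= 2 model frames")
  key <- function(f) paste(f$Participant, f$TokenType, f$Rate, sep = ".")
  ref <- frames[[1L]][order(key(frames[[1L]])), ]
  for (nm in names(frames)[-1L]) {
    f <- frames[[nm]][order(key(frames[[nm]])), ]
    if (nrow(f) != nrow(ref) ||
        !isTRUE(all.equal(f$Duration, ref$Duration, tolerance = 1e-9)))
      .stop_data("response rows differ between variant '", names(frames)[1L],
                 "' and '", nm, "'")
  }
  fits <- lapply(frames, function(f)
    lme4::lmer(Duration ~ DisplacementRange * Rate +
                 (1 + DisplacementRange | Participant),
               data = f, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")))
  tab <- data.frame(
    sensor_set = names(frames),
    df = vapply(fits, function(f) attr(stats::logLik(f), "df"), numeric(1)),
    AIC = vapply(fits, stats::AIC, numeric(1)),
    BIC = vapply(fits, stats::BIC, numeric(1)),
    logLik = vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1)),
    stringsAsFactors = FALSE)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$best <- tab$dAIC < 1e-6
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  attr(tab, "winner") <- tab$sensor_set[1L]
  attr(tab, "tied") <- sum(tab$best) > 1L
  tab
}

#' Build the fluctuation model frame
#'
#' Joins the tongue-front fluctuation series with the scaled tongue-front
#' displacement range (`TFd`: the per participant x token-type range,
#' z-scaled across cells), ordered by token then fluctuation time slice,
#' with `series_start` marking each token's first window for the AR(1)
#' correction.
#'
#' @param fluct Data frame from [fluctuation_table()].
#' @param ranges Output of [displacement_range()].
#' @param sensor_set Variant supplying the range; default `"tongue_front"`.
#' @return Data frame with `Fluctuation`, `FTS`, `TFd`, `SPS`, `TokenType`,
#'   `Participant`, `series_start`.
#' @export
fluctuation_model_frame <- function(fluct, ranges,
                                    sensor_set = "tongue_front") {
  rg <- ranges[ranges$sensor_set == sensor_set & !ranges$absent, ]
  if (!nrow(rg)) .stop_data("no ranges for sensor set '", sensor_set, "'")
  key_f <- paste(fluct$participant, fluct$token_type, sep = ".")
  key_r <- paste(rg$participant, rg$token_type, sep = ".")
  tfd_raw <- rg$range_value[match(key_f, key_r)]
  keep <- !is.na(tfd_raw)
  fl <- fluct[keep, ]
  tfd_raw <- tfd_raw[keep]
  if (!nrow(fl)) .stop_data("no fluctuation rows with a displacement range")
  tok <- paste(fl$participant, fl$token_type, fl$block, fl$rate, sep = ".")
  ord <- order(tok, fl$fts_index)
  fl <- fl[ord, ]; tfd_raw <- tfd_raw[ord]; tok <- tok[ord]
  data.frame(Fluctuation = fl$F_front,
             FTS = as.numeric(fl$fts_index),
             TFd = as.numeric(scale(tfd_raw)),
             SPS = as.numeric(fl$rate),
             TokenType = factor(fl$token_type),
             Participant = factor(fl$participant),
             series_start = !duplicated(tok),
             stringsAsFactors = FALSE)
}

## lag-1 autocorrelation of residuals within series (pairs spanning a
## series start are excluded)
.lag1_acf <- function(res, start) {
  ok <- !start[-1L]
  a <- res[-length(res)][ok]; b <- res[-1L][ok]
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Fit the fluctuation GAMM
#'
#' `Fluctuation ~ te(FTS, TFd) + s(FTS, TFd, Participant, bs = "fs", m = 1)
#' + s(SPS, Participant, bs = "re") + s(TokenType, Participant, bs = "re")`,
#' fitted with [mgcv::bam()]. The model is fitted twice: the first pass
#' estimates the lag-1 residual autocorrelation rho, the second refits with
#' the AR(1) correction (`rho`, `AR.start = series_start`), which removes
#' most of the residual autocorrelation.
#'
#' @param frame Data frame from [fluctuation_model_frame()].
#' @param k_te Basis dimensions for the tensor-product smooth (length 2).
#' @param k_fs Basis dimension for the factor-smooth participant term.
#' @param rho AR(1) parameter; `NULL` (default) estimates it from the first
#'   pass, `0` disables the correction.
#' @return An object of class `fluctuation_gamm`: list with `fit` (second
#'   pass), `fit_uncorrected`, `rho`, `smooth_table` (edf, Ref.df, F,
#'   p-value), `r2_adj`, `dev_expl`, `acf_uncorrected`, `acf_corrected`.
#' @export
fit_fluctuation_gamm <- function(frame, k_te = c(8, 5), k_fs = 5,
                                 rho = NULL) {
  need <- c("Fluctuation", "FTS", "TFd", "SPS", "TokenType", "Participant",
            "series_start")
  if (!all(need %in% names(frame)))
    .stop_data("frame must carry ", paste(need, collapse = ", "))
  if (any(!is.finite(frame$Fluctuation)))
    .stop_data("non-finite Fluctuation values")
  if (!any(frame$series_start))
    .stop_data("series_start must mark each token's first window")
  if (nlevels(droplevels(frame$Participant)) < 2L)
    .stop_data("need >= 2 participants")
  form <- Fluctuation ~ te(FTS, TFd, k = k_te) +
    s(FTS, TFd, Participant, bs = "fs", m = 1, k = k_fs) +
    s(SPS, Participant, bs = "re") +
    s(TokenType, Participant, bs = "re")
  env <- list2env(list(k_te = k_te, k_fs = k_fs), parent = environment())
  environment(form) <- env
  m1 <- mgcv::bam(form, data = frame, method = "fREML")
  r1 <- stats::residuals(m1)
  acf1 <- .lag1_acf(r1, frame$series_start)
  if (is.null(rho)) rho <- acf1
  m2 <- mgcv::bam(form, data = frame, method = "fREML",
                  rho = rho, AR.start = frame$series_start)
  ## AR-whitened residuals of the corrected fit
  r2v <- stats::residuals(m2)
  w <- r2v[-1L] - rho * r2v[-length(r2v)]
  w <- c(r2v[1L], ifelse(frame$series_start[-1L], r2v[-1L], w))
  acf2 <- .lag1_acf(w, frame$series_start)
  sm <- summary(m2)
  st <- as.data.frame(sm$s.table)
  structure(list(fit = m2, fit_uncorrected = m1, rho = rho,
                 smooth_table = st, r2_adj = sm$r.sq,
                 dev_expl = sm$dev.expl,
                 acf_uncorrected = acf1, acf_corrected = acf2),
            class = "fluctuation_gamm")
}

#' @export
print.fluctuation_gamm <- function(x, ...) {
  cat("Fluctuation GAMM: te(FTS, TFd) + fs/re participant smooths,",
      sprintf("AR(1) rho = %.3f\n", x$rho))
  print(round(x$smooth_table, 3))
  cat(sprintf("adjusted r2 = %.3f, deviance explained = %.1f%%\n",
              x$r2_adj, 100 * x$dev_expl))
  cat(sprintf("lag-1 residual acf: %.3f (uncorrected) -> %.3f (corrected)\n",
              x$acf_uncorrected, x$acf_corrected))
  invisible(x)
}

#' Predicted fluctuation surface
#'
#' Evaluates the population-level tensor surface (intercept + `te(FTS,
#' TFd)`, random-effect smooths excluded) over a grid, for inspecting where
#' in the token time course fluctuation concentrates at each displacement
#' range.
#'
#' @param model A `fluctuation_gamm`.
#' @param fts Grid of fluctuation time slices; default 1..23.
#' @param tfd Grid of scaled displacement ranges; default 25 points spanning
#'   the fitted range.
#' @return Data frame with `FTS`, `TFd`, `F_hat`.
#' @export
predict_fluctuation_surface <- function(model, fts = NULL, tfd = NULL) {
  stopifnot(inherits(model, "fluctuation_gamm"))
  dat <- model$fit$model
  if (is.null(fts)) fts <- seq(min(dat$FTS), max(dat$FTS), by = 1)
  if (is.null(tfd)) tfd <- seq(min(dat$TFd), max(dat$TFd), length.out = 25L)
  nd <- expand.grid(FTS = fts, TFd = tfd)
  nd$SPS <- stats::median(dat$SPS)
  nd$TokenType <- dat$TokenType[1L]
  nd$Participant <- dat$Participant[1L]
  excl <- grep("Participant", rownames(model$smooth_table), value = TRUE)
  nd$F_hat <- as.vector(stats::predict(model$fit, newdata = nd,
                                       exclude = excl))
  nd[, c("FTS", "TFd", "F_hat")]
}
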