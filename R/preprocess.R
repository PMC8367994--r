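## preprocess: DCT penalized-least-squares smoothing with missing-sample
## restoration, rigid alignment to the idealized occlusal plane, and palate
## trace estimation.
##
## The smoother minimizes ||y - z||^2 (over observed samples) +
## lambda ||D2 z||^2, whose solution is diagonal in the DCT-II basis:
## z = IDCT(Gamma * DCT(y)), Gamma_k = 1 / (1 + lambda * L_k^2),
## L_k = -2 + 2 cos((k-1) pi / n). Missing samples are restored by fixed-point
## iteration on the weighted residual; lambda = "auto" is chosen by
## generalized cross-validation. Token series are short (~40-150 samples at
## 100 Hz) so the DCT is applied as an orthonormal matrix product, cached per
## length.

.dct_cache <- new.env(parent = emptyenv())

.dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dct_cache[[key]])) return(.dct_cache[[key]])
  k <- 0:(n - 1L)
  C <- sqrt(2 / n) * cos(pi * outer(k, (2 * k + 1) / (2 * n)))
  C[1L, ] <- C[1L, ] / sqrt(2)
  .dct_cache[[key]] <- C
  C
}

.dct_eigen <- function(n) -2 + 2 * cos((0:(n - 1L)) * pi / n)

## one smoothing pass at fixed lambda on a fully observed vector
.dct_pass <- function(y, C, gamma) drop(crossprod(C, gamma * (C %*% y)))

.gcv_lambda <- function(y, C, L, interval = c(-8, 8)) {
  n <- length(y)
  a <- drop(C %*% y)
  gcv <- function(log10s) {
    g <- 1 / (1 + 10^log10s * L^2)
    rss <- sum(((g - 1) * a)^2)     # Parseval: residual in DCT domain
    trh <- sum(g)
    n * rss / (n - trh)^2
  }
  10^stats::optimize(gcv, interval)$minimum
}

.smooth_vector <- function(y, valid, lambda) {
  n <- length(y)
  C <- .dct_matrix(n)
  L <- .dct_eigen(n)
  idx <- seq_len(n)
  if (any(!valid)) {
    ## initial fill: linear interpolation over gaps, edges held constant
    filled <- stats::approx(idx[valid], y[valid], xout = idx,
                            rule = 2)$y
  } else filled <- y
  if (identical(lambda, "auto")) lambda <- .gcv_lambda(filled, C, L)
  gamma <- 1 / (1 + lambda * L^2)
  if (!any(!valid)) return(list(z = .dct_pass(y, C, gamma), lambda = lambda))
  ## fixed-point iteration: z <- S(w*(y - z) + z), w = 1 on observed samples
  w <- as.numeric(valid)
  y0 <- y; y0[!valid] <- 0
  z <- filled
  for (it in seq_len(200L)) {
    z_new <- .dct_pass(w * (y0 - z) + z, C, gamma)
    if (max(abs(z_new - z)) < 1e-10 * (1 + max(abs(z_new)))) { z <- z_new; break }
    z <- z_new
  }
  list(z = z, lambda = lambda)
}

#' Smoother configuration
#'
#' @param lambda Nonnegative smoothing penalty, or `"auto"` (default) to
#'   select by generalized cross-validation per coordinate.
#' @param max_gap Longest run of missing samples (in samples) the smoother is
#'   allowed to restore; longer gaps raise a data error.
#' @return An object of class `smoother_config`.
#' @export
smoother_config <- function(lambda = "auto", max_gap = 20L) {
  if (!identical(lambda, "auto")) {
    lambda <- as.numeric(lambda)
    if (is.na(lambda) || lambda < 0) .stop_data("lambda must be >= 0 or 'auto'")
  }
  structure(list(lambda = lambda, max_gap = as.integer(max_gap)),
            class = "smoother_config")
}

.gap_runs <- function(valid) {
  r <- rle(!valid)
  if (!any(r$values)) return(integer(0))
  r$lengths[r$values]
}

#' DCT penalized-least-squares smoothing of a trajectory
#'
#' Low-pass filters a sensor trajectory and restores missing samples in one
#' pass (smoothing and gap restoration share the same penalized
#' least-squares solution, diagonalized by the discrete cosine transform).
#' The time vector is never altered; the output mask is all-valid. x and y
#' are smoothed per coordinate.
#'
#' @param traj A [sensor_trajectory].
#' @param cfg A [smoother_config].
#' @return A [sensor_trajectory] with restored, smoothed positions.
#' @export
dct_smooth <- function(traj, cfg = smoother_config()) {
  stopifnot(inherits(traj, "sensor_trajectory"))
  if (!inherits(cfg, "smoother_config")) .stop_data("cfg must be a smoother_config")
  nv <- sum(traj$valid)
  if (nv < 10L)
    .stop_data("sensor ", traj$sensor_id, ": only ", nv,
               " valid samples (need >= 10)")
  gaps <- .gap_runs(traj$valid)
  if (length(gaps) && max(gaps) > cfg$max_gap) {
    r <- rle(!traj$valid)
    ends <- cumsum(r$lengths)
    i <- which(r$values & r$lengths > cfg$max_gap)[1L]
    .stop_data("sensor ", traj$sensor_id, ": missing run of ", r$lengths[i],
               " samples (t = ", signif(traj$times[ends[i] - r$lengths[i] + 1L], 6),
               "..", signif(traj$times[ends[i]], 6), " s) exceeds max_gap = ",
               cfg$max_gap)
  }
  pos <- traj$positions
  pos[!traj$valid, ] <- NA_real_
  out <- pos
  lambdas <- numeric(2)
  for (j in 1:2) {
    sm <- .smooth_vector(ifelse(is.na(pos[, j]), 0, pos[, j]),
                         traj$valid & !is.na(pos[, j]), cfg$lambda)
    out[, j] <- sm$z
    lambdas[j] <- sm$lambda
  }
  res <- sensor_trajectory(traj$sensor_id, traj$times, out)
  attr(res, "lambda") <- lambdas
  res
}

#' Rigid transform in the midsagittal plane
#'
#' Rotation (radians, counter-clockwise) followed by translation
#' (millimetres). Distance-preserving by construction.
#'
#' @param rotation Rotation angle in radians.
#' @param translation Numeric length-2 translation (x, y) in millimetres.
#' @return An object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(rotation = 0, translation = c(0, 0)) {
  rotation <- as.numeric(rotation)
  translation <- as.numeric(translation)
  if (length(rotation) != 1L || !is.finite(rotation) ||
      length(translation) != 2L || any(!is.finite(translation)))
    .stop_data("rotation must be a finite scalar and translation length-2")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform2d")
}

.rot_mat <- function(phi) matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L)

#' Compose two rigid transforms
#'
#' `transform_compose(a, b)` returns the transform equivalent to applying
#' `a` first, then `b`.
#'
#' @param a,b [rigid_transform2d] objects.
#' @return A [rigid_transform2d].
#' @export
transform_compose <- function(a, b) {
  Rb <- .rot_mat(b$rotation)
  rigid_transform2d(a$rotation + b$rotation,
                    drop(Rb %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#'
#' @param t A [rigid_transform2d].
#' @return The inverse [rigid_transform2d].
#' @export
transform_invert <- function(t) {
  Ri <- .rot_mat(-t$rotation)
  rigid_transform2d(-t$rotation, -drop(Ri %*% t$translation))
}

#' Apply a rigid transform
#'
#' Applies a [rigid_transform2d] to an N x 2 position matrix, a
#' [sensor_trajectory], or every sensor of a [token_recording] (landmarks
#' and metadata unchanged).
#'
#' @param t A [rigid_transform2d].
#' @param x Positions matrix, trajectory, or recording.
#' @return Object of the same type as `x`, transformed.
#' @export
apply_transform <- function(t, x) UseMethod("apply_transform", x)

#' @export
apply_transform.matrix <- function(t, x) {
  R <- .rot_mat(t$rotation)
  sweep(x %*% t(R), 2L, t$translation, "+")
}

#' @export
apply_transform.sensor_trajectory <- function(t, x) {
  pos <- x$positions
  ok <- stats::complete.cases(pos)
  pos[ok, ] <- apply_transform.matrix(t, pos[ok, , drop = FALSE])
  out <- x
  out$positions <- pos
  out
}

#' @export
apply_transform.token_recording <- function(t, x) {
  x$trajectories <- lapply(x$trajectories, function(tr) apply_transform(t, tr))
  x
}

#' Estimate the occlusal-plane transform
#'
#' Estimates the rigid transform taking recorded bite-plane points onto the
#' idealized flat occlusal plane `y = 0` with the anterior direction at
#' positive x ("tongue tip facing forward"). The first bite point is taken
#' as the anterior one. An optional head-reference point set (e.g. nasion
#' and mastoid markers) is checked to map above the plane; a warning is
#' issued if it cannot (a proper rotation cannot fix both orientations).
#'
#' @param bite_points Numeric matrix (>= 2 rows, 2 columns) of recorded
#'   bite-plane points in millimetres; row 1 is the anterior point.
#' @param head_ref Optional matrix of head-reference points used as a
#'   superior-direction check.
#' @return A [rigid_transform2d] with attribute `residual` (root-mean-square
#'   y of the transformed bite points).
#' @export
estimate_occlusal_transform <- function(bite_points, head_ref = NULL) {
  bp <- as.matrix(bite_points)
  storage.mode(bp) <- "double"
  if (ncol(bp) != 2L || nrow(bp) < 2L)
    .stop_data("bite_points must be an n>=2 by 2 matrix")
  ctr <- colMeans(bp)
  cc <- sweep(bp, 2L, ctr)
  if (max(abs(cc)) < 1e-9)
    .stop_data("degenerate geometry: bite points are coincident")
  dir <- if (nrow(bp) == 2L) bp[1L, ] - bp[2L, ]
         else {
           v <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1L]
           if (sum(v * (bp[1L, ] - ctr)) < 0) -v else v
         }
  if (sqrt(sum(dir^2)) < 1e-9)
    .stop_data("degenerate geometry: cannot orient bite plane")
  phi <- -atan2(dir[2L], dir[1L])
  R <- .rot_mat(phi)
  ty <- -(drop(R %*% ctr))[2L]
  t <- rigid_transform2d(phi, c(0, ty))
  tb <- apply_transform(t, bp)
  attr(t, "residual") <- sqrt(mean(tb[, 2L]^2))
  if (!is.null(head_ref)) {
    hr <- apply_transform(t, as.matrix(head_ref))
    if (mean(hr[, 2L]) <= 0)
      warning("head reference maps below the occlusal plane; ",
              "check calibration point order", call. = FALSE)
  }
  t
}

#' Estimate a palate trace from tongue sensor positions
#'
#' Bins tongue-sensor samples along x and reports, per bin, the maximum y
#' after robust outlier trimming (samples beyond `mad_k`
#' median-absolute-deviations of the bin median y are discarded). Empty bins
#' are omitted, never interpolated.
#'
#' @param recs List of [token_recording] objects.
#' @param bin_mm Bin width along x in millimetres.
#' @param mad_k Trimming multiplier on the bin MAD.
#' @param sensors Sensors to pool; defaults to the tongue sensors.
#' @return Data frame with columns `x_mm` (bin centre), `y_mm` (trimmed
#'   maximum) and `n` (post-trim support count).
#' @export
estimate_palate <- function(recs, bin_mm = 1, mad_k = 3,
                            sensors = TONGUE_SENSORS) {
  if (inherits(recs, "token_recording")) recs <- list(recs)
  if (!length(recs)) .stop_data("need at least one recording")
  xs <- ys <- numeric(0)
  for (rec in recs) for (s in intersect(sensors, names(rec$trajectories))) {
    tr <- rec$trajectories[[s]]
    ok <- tr$valid & stats::complete.cases(tr$positions)
    xs <- c(xs, tr$positions[ok, 1L])
    ys <- c(ys, tr$positions[ok, 2L])
  }
  if (!length(xs)) .stop_data("no valid tongue sensor samples found")
  bin <- floor(xs / bin_mm)
  out <- lapply(sort(unique(bin)), function(b) {
    y <- ys[bin == b]
    med <- stats::median(y)
    md <- stats::mad(y)
    keep <- if (md < 1e-12) rep(TRUE, length(y)) else abs(y - med) <= mad_k * md
    data.frame(x_mm = (b + 0.5) * bin_mm, y_mm = max(y[keep]),
               n = sum(keep))
  })
  do.call(rbind, out)
}

#' Smooth and align a token recording
#'
#' Convenience stage: smooths every sensor trajectory with [dct_smooth()]
#' and applies an occlusal-plane transform.
#'
#' @param rec A [token_recording].
#' @param cfg A [smoother_config].
#' @param transform A [rigid_transform2d]; identity by default.
#' @param sensors Sensors to process (others are dropped); default all
#'   present.
#' @return A [token_recording] with smoothed, aligned trajectories.
#' @export
preprocess_recording <- function(rec, cfg = smoother_config(),
                                 transform = rigid_transform2d(),
                                 sensors = names(rec$trajectories)) {
  trajs <- lapply(rec$trajectories[intersect(sensors, names(rec$trajectories))],
                  dct_smooth, cfg = cfg)
  out <- rec
  out$trajectories <- trajs
  apply_transform(transform, out)
}
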