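## displacement: cumulative path metrics over the 31 Procrustean slices and
## their z-scored combination into tongue-front displacement T and the
## per-speaker, per-token-type displacement range.
##
## D is the sum of the 30 inter-slice Euclidean step lengths (millimetres);
## Theta the sum of the 29 unsigned turning angles between consecutive step
## vectors (radians, each angle the smaller of the two possibilities, so
## never more than pi). Because millimetres and radians are unrelated
## scales, each metric is z-scored over the whole dataset before summing;
## the four-component tongue-front sum is z-scored once more, so T is in
## standard-deviation units.

#' Sensor sets for the displacement variants
#'
#' The four sensor groupings over which displacement is combined:
#' tongue tip only, tongue front (tip + body), whole tongue (+ dorsum), and
#' whole vocal tract (+ lower incisor and both lips).
#'
#' @format Named list of character vectors.
#' @export
DISPLACEMENT_SENSOR_SETS <- list(
  tip = "TT",
  tongue_front = c("TT", "TB"),
  whole_tongue = c("TT", "TB", "TD"),
  whole_tract = c("TT", "TB", "TD", "LI", "UL", "LL")
)

.check_path <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) != N_SLICES || ncol(positions) != 2L)
    .stop_data("expected a ", N_SLICES, " x 2 position matrix, got ",
               nrow(positions), " x ", ncol(positions))
  if (any(!is.finite(positions))) .stop_data("positions must be finite")
  positions
}

#' Cumulative path distance over the Procrustean slices
#'
#' Sum of the 30 inter-slice Euclidean step lengths.
#'
#' @param positions 31 x 2 position matrix (millimetres).
#' @return Distance in millimetres.
#' @export
path_distance <- function(positions) {
  positions <- .check_path(positions)
  steps <- diff(positions)
  sum(sqrt(rowSums(steps^2)))
}

## signed turning angles between consecutive step vectors, in (-pi, pi],
## counter-clockwise positive in the x-anterior / y-superior frame.
## Zero-length steps yield angle 0 with a flag.
.step_turning <- function(positions, eps = 1e-12) {
  v <- diff(positions)
  a <- v[-nrow(v), , drop = FALSE]
  b <- v[-1L, , drop = FALSE]
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  degenerate <- na < eps | nb < eps
  ang <- atan2(a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L],
               rowSums(a * b))
  ang[degenerate] <- 0
  list(angle = ang, degenerate = degenerate)
}

#' Cumulative angular displacement over the Procrustean slices
#'
#' Sum of the 29 unsigned turning angles between consecutive inter-slice
#' step vectors; each angle is the smaller of the two possibilities and so
#' lies in `[0, pi]`. A zero-length step (stationary articulator) makes the
#' turning angle undefined and contributes 0.
#'
#' @param positions 31 x 2 position matrix (millimetres).
#' @return Angular displacement in radians, in `[0, 29*pi]`.
#' @export
path_angular_displacement <- function(positions) {
  positions <- .check_path(positions)
  sum(abs(.step_turning(positions)$angle))
}

#' Fit pooled z-score parameters
#'
#' Mean and sample (n-1) standard deviation over the pooled values (all
#' token instances and all participants).
#'
#' @param values Numeric vector of pooled values.
#' @param population Optional description of the pooling scope, kept with
#'   the parameters.
#' @return An object of class `zscore_params` with fields `mu`, `sigma`,
#'   `population`.
#' @export
zscore_fit <- function(values, population = "all tokens, all participants") {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    .stop_data("need at least 2 pooled values to fit z-score parameters")
  sigma <- stats::sd(values)
  if (!is.finite(sigma) || sigma <= 0)
    .stop_data("degenerate data: pooled standard deviation is zero")
  structure(list(mu = mean(values), sigma = sigma, population = population),
            class = "zscore_params")
}

#' Apply pooled z-score parameters
#'
#' @param p A `zscore_params` object from [zscore_fit()].
#' @param x Values to transform.
#' @return `(x - mu) / sigma`, in standard-deviation units.
#' @export
zscore_apply <- function(p, x) {
  stopifnot(inherits(p, "zscore_params"))
  (x - p$mu) / p$sigma
}

#' Per-token, per-sensor path metrics
#'
#' Computes D and Theta for every sensor of every Procrustean token.
#'
#' @param ptokens List of `procrustean_token` objects.
#' @return Data frame with metadata columns plus `sensor`, `D_mm`,
#'   `Theta_rad`, `duration`.
#' @export
path_metrics <- function(ptokens) {
  if (inherits(ptokens, "procrustean_token")) ptokens <- list(ptokens)
  rows <- lapply(ptokens, function(pt) {
    do.call(rbind, lapply(names(pt$positions), function(s) {
      data.frame(participant = pt$participant, token_type = pt$token_type,
                 block = pt$block, rate = pt$rate, sensor = s,
                 D_mm = path_distance(pt$positions[[s]]),
                 Theta_rad = path_angular_displacement(pt$positions[[s]]),
                 duration = pt$duration, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## reshape the metrics table to one row per token with D/Theta per sensor
.metrics_wide <- function(metrics, sensors) {
  missing_s <- setdiff(sensors, unique(metrics$sensor))
  if (length(missing_s))
    .stop_data("metrics table lacks sensor(s): ",
               paste(missing_s, collapse = ", "))
  key <- paste(metrics$participant, metrics$token_type, metrics$block,
               metrics$rate, sep = ".")
  base <- metrics[!duplicated(key),
                  c("participant", "token_type", "block", "rate", "duration")]
  base$token <- unique(key)
  rownames(base) <- base$token
  for (s in sensors) {
    ms <- metrics[metrics$sensor == s, ]
    ks <- paste(ms$participant, ms$token_type, ms$block, ms$rate, sep = ".")
    if (anyDuplicated(ks))
      .stop_data("duplicate metric rows for sensor ", s)
    miss <- setdiff(base$token, ks)
    if (length(miss))
      .stop_data("token ", miss[1L], " missing component for sensor ", s)
    base[[paste0("D_", s)]] <- ms$D_mm[match(base$token, ks)]
    base[[paste0("Theta_", s)]] <- ms$Theta_rad[match(base$token, ks)]
  }
  base
}

#' Combined displacement for a sensor set
#'
#' For each token, z-scores every per-sensor D and Theta over the whole
#' dataset, sums the components for the requested sensor set, and z-scores
#' the sum again, yielding the combined displacement T in
#' standard-deviation units. With the default `sensors = c("TT", "TB")`
#' this is the tongue-front displacement.
#'
#' @param metrics Data frame from [path_metrics()].
#' @param sensors Character vector of sensors to combine.
#' @param sensor_set Label stored in the output (defaults to the matching
#'   name in [DISPLACEMENT_SENSOR_SETS], else the sensors pasted together).
#' @return Data frame with one row per token: metadata, the per-component
#'   z-scores (`z_D_<sensor>`, `z_Theta_<sensor>`), the component sum
#'   `sum_z` and `T`. The fitted `zscore_params` are attached as attribute
#'   `params`.
#' @export
tongue_front_displacement <- function(metrics, sensors = c("TT", "TB"),
                                      sensor_set = NULL) {
  if (is.null(sensor_set)) {
    hit <- vapply(DISPLACEMENT_SENSOR_SETS, setequal, logical(1), sensors)
    sensor_set <- if (any(hit)) names(DISPLACEMENT_SENSOR_SETS)[which(hit)[1L]]
                  else paste(sensors, collapse = "+")
  }
  wide <- .metrics_wide(metrics, sensors)
  params <- list()
  zsum <- 0
  for (s in sensors) for (mtr in c("D", "Theta")) {
    col <- paste0(mtr, "_", s)
    p <- zscore_fit(wide[[col]])
    params[[col]] <- p
    z <- zscore_apply(p, wide[[col]])
    wide[[paste0("z_", col)]] <- z
    zsum <- zsum + z
  }
  wide$sum_z <- zsum
  p_outer <- zscore_fit(zsum, population = "four-component sums, all tokens")
  params$outer <- p_outer
  wide$T <- zscore_apply(p_outer, zsum)
  wide$sensor_set <- sensor_set
  rownames(wide) <- NULL
  structure(wide[, c("participant", "token_type", "block", "rate",
                     "sensor_set", "duration",
                     grep("^z_", names(wide), value = TRUE),
                     "sum_z", "T")],
            params = params)
}

#' Displacement summaries for the four sensor-set variants
#'
#' Runs [tongue_front_displacement()] once per variant in
#' [DISPLACEMENT_SENSOR_SETS] (z-scores refit per variant) and stacks the
#' results. Variants whose sensors are not all present are skipped with a
#' message.
#'
#' @param metrics Data frame from [path_metrics()].
#' @param sets Named list of sensor sets; defaults to
#'   [DISPLACEMENT_SENSOR_SETS].
#' @return Data frame with one row per token x variant (z-component columns
#'   restricted to those shared by all variants are dropped; `sum_z` and
#'   `T` retained).
#' @export
displacement_summary <- function(metrics, sets = DISPLACEMENT_SENSOR_SETS) {
  have <- unique(metrics$sensor)
  rows <- lapply(names(sets), function(nm) {
    if (!all(sets[[nm]] %in% have)) {
      message("skipping variant '", nm, "': sensor(s) ",
              paste(setdiff(sets[[nm]], have), collapse = ", "), " absent")
      return(NULL)
    }
    d <- tongue_front_displacement(metrics, sets[[nm]], sensor_set = nm)
    d[, c("participant", "token_type", "block", "rate", "sensor_set",
          "duration", "sum_z", "T")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Displacement range per participant and token type
#'
#' Mean combined displacement T of the tokens prompted at 3 syllables/s
#' minus the mean at 7 syllables/s, per participant x token type (and per
#' sensor-set variant when several are present). Cells lacking tokens at
#' either extreme rate are reported with `range_value = NA` and
#' `absent = TRUE`, never imputed.
#'
#' @param t_table Data frame from [tongue_front_displacement()] or
#'   [displacement_summary()].
#' @return Data frame with columns `participant`, `token_type`,
#'   `sensor_set`, `mean_T_3`, `mean_T_7`, `range_value`, `absent`.
#' @export
displacement_range <- function(t_table) {
  need <- c("participant", "token_type", "rate", "T")
  if (!all(need %in% names(t_table)))
    .stop_data("t_table must carry columns ", paste(need, collapse = ", "))
  if (is.null(t_table$sensor_set)) t_table$sensor_set <- "tongue_front"
  cells <- unique(t_table[, c("participant", "token_type", "sensor_set")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sub <- t_table[t_table$participant == cl$participant &
                     t_table$token_type == cl$token_type &
                     t_table$sensor_set == cl$sensor_set, ]
    m3 <- mean(sub$T[sub$rate == 3])
    m7 <- mean(sub$T[sub$rate == 7])
    absent <- is.nan(m3) || is.nan(m7)
    data.frame(participant = cl$participant, token_type = cl$token_type,
               sensor_set = cl$sensor_set,
               mean_T_3 = if (is.nan(m3)) NA_real_ else m3,
               mean_T_7 = if (is.nan(m7)) NA_real_ else m7,
               range_value = if (absent) NA_real_ else m3 - m7,
               absent = absent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
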