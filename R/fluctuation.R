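## fluctuation: the windowed critical-fluctuation statistic F over the
## signed turning-angle series of each token.
##
## F sums, over the monotone periods of a 7-sample window, the absolute
## value change per unit (transformed) time, normalized by s*(m-1) where s
## is the full scale width (2*pi for signed angles in (-pi, pi]). Window
## times are mapped affinely so the smallest inter-sample gap equals 1;
## on a uniform grid this reduces exactly to the integer-index formula
## (n = 1..m), and it keeps every period's time extent >= 1, which together
## with |dx| <= s and at most m-1 periods guarantees 0 <= F <= 1 for any
## strictly increasing times. The map is invariant to affine changes of the
## raw time axis.

#' Signed turning angles of a Procrustean path
#'
#' Signed turning angle between each pair of consecutive inter-slice step
#' vectors, counter-clockwise positive in the x-anterior / y-superior frame,
#' in `(-pi, pi]`. Absolute values equal the per-step angles summed by
#' [path_angular_displacement()]. A zero-length step yields angle 0 and is
#' flagged. Each angle is timestamped at its vertex slice (slice `i + 1` for
#' angle `i`).
#'
#' @param positions 31 x 2 position matrix (millimetres).
#' @param times Optional vector of 31 slice times; angle times are returned
#'   when given.
#' @return Data frame with columns `angle` (29 radians), `degenerate`
#'   (logical flag for zero-length steps) and, when `times` is supplied,
#'   `time_s`.
#' @export
signed_step_angles <- function(positions, times = NULL) {
  positions <- .check_path(positions)
  st <- .step_turning(positions)
  out <- data.frame(angle = st$angle, degenerate = st$degenerate)
  if (!is.null(times)) {
    if (length(times) != N_SLICES)
      .stop_data("times must have ", N_SLICES, " entries")
    out$time_s <- times[2:(N_SLICES - 1L)]
  }
  out
}

#' Points of return in a window
#'
#' Indices where the series' first difference changes sign, delimiting the
#' maximal monotone periods F sums over. Plateaus (zero first difference)
#' continue the previous direction; a leading plateau takes the direction of
#' the first nonzero difference; an all-constant window is a single period.
#'
#' @param x Numeric window values.
#' @return List with `k_indices` (interior return-point sample indices),
#'   `l` (number of periods) and `boundaries` (period boundary indices,
#'   starting at 1 and ending at `length(x)`).
#' @export
points_of_return <- function(x) {
  m <- length(x)
  if (m < 2L) return(list(k_indices = integer(0), l = 1L,
                          boundaries = c(1L, m)))
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (!length(nz))
    return(list(k_indices = integer(0), l = 1L, boundaries = c(1L, m)))
  ## leading plateau takes the first nonzero direction; later plateaus
  ## carry the previous direction forward
  s[seq_len(nz[1L] - 1L)] <- s[nz[1L]]
  for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  k <- which(diff(s) != 0) + 1L   # sample index where direction changes
  list(k_indices = k, l = length(k) + 1L,
       boundaries = c(1L, k, m))
}

#' Windowed critical-fluctuation statistic
#'
#' Evaluates F on one window of `m` values on the bounded scale
#' `[x_min, x_max]`: per monotone period, the absolute value change divided
#' by its transformed time extent, summed and normalized by
#' `(x_max - x_min) * (m - 1)`. Window times are mapped affinely so the
#' smallest gap equals 1 (uniform grids reduce to integer indices
#' `1..m`), which guarantees `0 <= F <= 1`.
#'
#' @param x Numeric window values within `[x_min, x_max]`.
#' @param n Strictly increasing time positions, same length as `x`. Integer
#'   indices `seq_along(x)` by default.
#' @param x_min,x_max Scale bounds; default `-pi`, `pi` (signed turning
#'   angles).
#' @return F, a unitless value in `[0, 1]`.
#' @export
fluctuation_F <- function(x, n = seq_along(x), x_min = -pi, x_max = pi) {
  m <- length(x)
  if (m < 2L) .stop_data("window needs at least 2 values")
  if (length(n) != m) .stop_data("x and n lengths differ")
  dn <- diff(n)
  if (any(dn <= 0)) .stop_data("window times must be strictly increasing")
  s <- x_max - x_min
  if (s <= 0) .stop_data("x_max must exceed x_min")
  if (any(x < x_min - 1e-9) || any(x > x_max + 1e-9))
    .stop_data("window values outside the scale [",
               signif(x_min, 6), ", ", signif(x_max, 6), "]")
  n2 <- c(0, cumsum(dn / min(dn)))  # min-gap-normalized times, origin-free
  b <- points_of_return(x)$boundaries
  sum(abs(diff(x[b])) / diff(n2[b])) / (s * (m - 1L))
}

#' Sliding fluctuation over a turning-angle series
#'
#' Slides a window of `m` consecutive angles (stride 1) along the 29-angle
#' series of a token and evaluates [fluctuation_F()] on each, yielding
#' `length(theta) - m + 1` fluctuation time slices (23 for the standard
#' series).
#'
#' @param theta Signed turning angles in `(-pi, pi]`.
#' @param times Angle time positions (strictly increasing), same length.
#' @param m Window length; default 7.
#' @return Data frame with `fts_index` (window start), `F`, `t_start`,
#'   `t_end`.
#' @export
sliding_fluctuation <- function(theta, times = seq_along(theta),
                                m = FLUCT_WINDOW) {
  nth <- length(theta)
  if (length(times) != nth) .stop_data("theta and times lengths differ")
  if (nth < m)
    .stop_data("need at least ", m, " angles for one window; got ", nth)
  idx <- seq_len(nth - m + 1L)
  F <- vapply(idx, function(i) {
    w <- i:(i + m - 1L)
    fluctuation_F(theta[w], times[w])
  }, numeric(1))
  data.frame(fts_index = idx, F = F,
             t_start = times[idx], t_end = times[idx + m - 1L])
}

#' Tongue-front fluctuation
#'
#' Elementwise mean of the tongue-tip and tongue-body F series, representing
#' tongue-front fluctuation with theoretical range `[0, 1]`.
#'
#' @param f_tt,f_tb Equal-length numeric F series.
#' @return Numeric vector of `(f_tt + f_tb) / 2`.
#' @export
tongue_front_fluctuation <- function(f_tt, f_tb) {
  if (length(f_tt) != length(f_tb))
    .stop_data("TT and TB fluctuation series lengths differ (",
               length(f_tt), " vs ", length(f_tb), ")")
  (f_tt + f_tb) / 2
}

#' Fluctuation series for one token
#'
#' Computes signed turning angles for the TT and TB paths of a Procrustean
#' token, slides the F window over each, and averages into the tongue-front
#' series.
#'
#' @param pt A `procrustean_token` (must carry TT and TB).
#' @param m Window length; default 7.
#' @return Data frame with metadata, `fts_index`, `F_TT`, `F_TB`, `F_front`
#'   and the window's slice time span.
#' @export
token_fluctuation <- function(pt, m = FLUCT_WINDOW) {
  stopifnot(inherits(pt, "procrustean_token"))
  if (!all(c("TT", "TB") %in% names(pt$positions)))
    .stop_data("token ", token_key(pt$participant, pt$token_type, pt$block,
                                   pt$rate), " lacks TT/TB positions")
  ser <- lapply(c("TT", "TB"), function(s) {
    ang <- signed_step_angles(pt$positions[[s]], pt$slice_times)
    sliding_fluctuation(ang$angle, ang$time_s, m = m)
  })
  data.frame(participant = pt$participant, token_type = pt$token_type,
             block = pt$block, rate = pt$rate,
             fts_index = ser[[1L]]$fts_index,
             F_TT = ser[[1L]]$F, F_TB = ser[[2L]]$F,
             F_front = tongue_front_fluctuation(ser[[1L]]$F, ser[[2L]]$F),
             t_start = ser[[1L]]$t_start, t_end = ser[[1L]]$t_end,
             stringsAsFactors = FALSE)
}

#' Fluctuation table for a set of tokens
#'
#' @param ptokens List of `procrustean_token` objects.
#' @param m Window length; default 7.
#' @return Stacked data frame of [token_fluctuation()] rows.
#' @export
fluctuation_table <- function(ptokens, m = FLUCT_WINDOW) {
  if (inherits(ptokens, "procrustean_token")) ptokens <- list(ptokens)
  out <- do.call(rbind, lapply(ptokens, token_fluctuation, m = m))
  rownames(out) <- NULL
  out
}
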