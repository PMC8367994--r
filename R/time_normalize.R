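## time_normalize: the Procrustean fit. Every token is reduced to 31
## landmark-anchored time slices -- 11 uniformly spaced from first-vowel
## onset to the first flap's intensity minimum (both ends included), 10 more
## completing uniform coverage to the second flap's minimum, and 10 more to
## the end of the third vowel -- so tokens at different speech rates are
## compared at the same relative timing.

#' Landmark-anchored slice times
#'
#' Returns the 31 Procrustean slice times for a landmark set: slices 1, 11,
#' 21 and 31 coincide with first-vowel onset, first-flap minimum,
#' second-flap minimum and third-vowel end; spacing is uniform within each
#' of the three segments (11/10/10 new points).
#'
#' @param lm A [landmark_set].
#' @return Numeric vector of 31 strictly increasing times in seconds.
#' @export
slice_times <- function(lm) {
  if (!inherits(lm, "landmark_set")) .stop_data("lm must be a landmark_set")
  c(seq(lm$v1_onset, lm$flap1_min, length.out = 11L),
    seq(lm$flap1_min, lm$flap2_min, length.out = 11L)[-1L],
    seq(lm$flap2_min, lm$v3_end, length.out = 11L)[-1L])
}

#' Token duration
#'
#' Duration of the analysed span: first-vowel onset to third-vowel end.
#'
#' @param lm A [landmark_set].
#' @return Duration in seconds.
#' @export
token_duration <- function(lm) {
  if (!inherits(lm, "landmark_set")) .stop_data("lm must be a landmark_set")
  lm$v3_end - lm$v1_onset
}

#' Resample a token at the Procrustean slice times
#'
#' Interpolates every sensor's (smoothed, gap-free) trajectory at the 31
#' slice times. Cubic spline interpolation is used when every landmark
#' segment holds at least 5 raw samples; otherwise linear interpolation (the
#' trajectory is too short for a stable cubic fit).
#'
#' @param rec A [token_recording] whose trajectories are fully valid (run
#'   [dct_smooth()] first if they are not).
#' @param method `"auto"` (default), `"cubic"` or `"linear"`.
#' @return An object of class `procrustean_token`: list with `slice_times`
#'   (31 values), `positions` (named list of 31 x 2 matrices per sensor),
#'   `duration`, and the token metadata.
#' @export
resample_token <- function(rec, method = c("auto", "cubic", "linear")) {
  stopifnot(inherits(rec, "token_recording"))
  method <- match.arg(method)
  st <- slice_times(rec$landmarks)
  lmv <- unlist(rec$landmarks)
  positions <- list()
  for (tr in rec$trajectories) {
    if (!all(tr$valid) || anyNA(tr$positions))
      .stop_data("sensor ", tr$sensor_id,
                 ": trajectory has missing samples; smooth before resampling")
    if (st[1L] < tr$times[1L] - 1e-9 ||
        st[N_SLICES] > tr$times[length(tr$times)] + 1e-9)
      .stop_data("slice times outside trajectory span for sensor ",
                 tr$sensor_id)
    m <- method
    if (m == "auto") {
      per_seg <- vapply(1:3, function(i)
        sum(tr$times >= lmv[i] & tr$times <= lmv[i + 1L]), integer(1))
      m <- if (min(per_seg) < 5L) "linear" else "cubic"
    }
    interp <- function(yy) {
      if (m == "cubic") stats::spline(tr$times, yy, xout = st,
                                      method = "fmm")$y
      else stats::approx(tr$times, yy, xout = st, rule = 2)$y
    }
    positions[[tr$sensor_id]] <- cbind(x = interp(tr$positions[, 1L]),
                                       y = interp(tr$positions[, 2L]))
  }
  structure(list(slice_times = st, positions = positions,
                 duration = token_duration(rec$landmarks),
                 participant = rec$participant, token_type = rec$token_type,
                 block = rec$block, rate = rec$rate),
            class = "procrustean_token")
}

#' @export
print.procrustean_token <- function(x, ...) {
  cat("<procrustean_token>", token_key(x$participant, x$token_type, x$block,
                                       x$rate),
      "sensors:", paste(names(x$positions), collapse = ","),
      sprintf("duration %.3f s\n", x$duration))
  invisible(x)
}

#' Long table of Procrustean slice positions
#'
#' @param ptokens List of `procrustean_token` objects.
#' @return Data frame with one row per token x sensor x slice: metadata,
#'   `slice_index` (1-31), `time_s`, `x_mm`, `y_mm`.
#' @export
procrustean_table <- function(ptokens) {
  if (inherits(ptokens, "procrustean_token")) ptokens <- list(ptokens)
  rows <- lapply(ptokens, function(pt) {
    do.call(rbind, lapply(names(pt$positions), function(s) {
      data.frame(participant = pt$participant, token_type = pt$token_type,
                 block = pt$block, rate = pt$rate, sensor = s,
                 slice_index = seq_len(N_SLICES), time_s = pt$slice_times,
                 x_mm = pt$positions[[s]][, 1L],
                 y_mm = pt$positions[[s]][, 2L],
                 duration = pt$duration, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
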