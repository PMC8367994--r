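## synthetic_data: deterministic synthetic cohorts with the statistical
## structure the analysis assumes.
##
## Each token's tongue-tip path is built from raised-cosine stroke
## primitives: three vowel postures joined by smooth anterior-posterior
## transitions, with two palate-directed excursions (the flaps) whose
## amplitude grows at slower prompted rates -- more for speakers with a
## wider programmed displacement range. Two-gait speakers switch to a
## categorically different slow-rate path (an added loop around the first
## flap) below a rate threshold. Effort placement is emulated by a localized
## high-frequency wiggle whose envelope sits early in the token
## (end-state comfort) or over the second flap (mid-token effort). The
## tongue body and dorsum are scaled, posteriorly shifted copies of the tip
## path, so tongue-front measures inherit the programmed structure; incisor
## and lip sensors carry small flap-synchronous movements. Gaussian sensor
## noise and bounded missing runs are injected per config. Everything is a
## pure function of the seed.

## raised-cosine bump: 1 at centre, 0 outside [centre - width, centre + width]
.rc_pulse <- function(tau, centre, width) {
  u <- (tau - centre) / width
  out <- numeric(length(tau))
  inside <- abs(u) < 1
  out[inside] <- 0.5 * (1 + cos(pi * u[inside]))
  out
}

## smooth monotone step from 0 to 1 centred on `centre`
.rc_step <- function(tau, centre, width) {
  u <- pmin(pmax((tau - centre) / width + 0.5, 0), 1)
  0.5 * (1 - cos(pi * u))
}

#' Speaker gait profiles
#'
#' Programmed per-speaker truth: the target tongue-front displacement range
#' (`base_range`, standard-deviation-unit scale), the widening of the
#' duration range with `base_range` (`duration_range_slope`), the gait count
#' (2 only above `gait_threshold`, mirroring wide-range speakers having a
#' categorically distinct slow gait) and the effort-placement profile:
#' speakers at both displacement-range extremes get `end_state_comfort`
#' (early-token effort), middling speakers `mid_token_effort` (effort over
#' the second flap).
#'
#' @param n_participants Number of speakers.
#' @param base_range Programmed ranges; default evenly spans 0.5 to 3.5.
#' @param gait_threshold `base_range` above which the speaker has two gaits.
#' @param duration_range_slope Seconds of extra duration range per unit of
#'   `base_range`.
#' @return Data frame with one row per participant.
#' @export
speaker_profiles <- function(n_participants = 11L,
                             base_range = seq(0.5, 3.5,
                                              length.out = n_participants),
                             gait_threshold = 2.4,
                             duration_range_slope = 0.14) {
  if (length(base_range) != n_participants)
    .stop_data("base_range must have one value per participant")
  terc <- cut(rank(base_range, ties.method = "first"),
              breaks = 3L, labels = c("low", "mid", "high"))
  data.frame(
    participant = sprintf("P%02d", seq_len(n_participants)),
    base_range = base_range,
    gait_count = ifelse(base_range > gait_threshold, 2L, 1L),
    duration_range_slope = duration_range_slope,
    esc_profile = ifelse(terc == "mid", "mid_token_effort",
                         "end_state_comfort"),
    stringsAsFactors = FALSE)
}

#' Cohort configuration
#'
#' Study-shaped defaults: 11 participants x 8 token types x 5 reiterant
#' rates (3-7 syllables/s) x 10 blocks at 100 Hz.
#'
#' @param n_participants,n_token_types,n_blocks Design counts.
#' @param rates Reiterant rates (syllables/s).
#' @param sample_rate Sampling rate in Hz.
#' @param noise_sd Gaussian sensor noise, millimetres.
#' @param dropout_prob Per-sensor probability of one missing run per token.
#' @param dropout_max Longest missing run, samples.
#' @param gait_rate_threshold Prompt rate below which two-gait speakers use
#'   the alternative slow gait.
#' @param effort_amp Amplitude (mm) of the effort-placement wiggle.
#' @param seed Integer seed; fully determines the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 11L, n_token_types = 8L,
                          rates = 3:7, n_blocks = 10L, sample_rate = 100,
                          noise_sd = 0.3, dropout_prob = 0.05,
                          dropout_max = 10L, gait_rate_threshold = 5,
                          effort_amp = 1.2, seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_token_types = as.integer(n_token_types),
              rates = as.integer(rates), n_blocks = as.integer(n_blocks),
              sample_rate = sample_rate, noise_sd = noise_sd,
              dropout_prob = dropout_prob,
              dropout_max = as.integer(dropout_max),
              gait_rate_threshold = gait_rate_threshold,
              effort_amp = effort_amp, seed = as.integer(seed))
  if (any(unlist(cfg[c("n_participants", "n_token_types", "n_blocks")]) < 1L))
    .stop_data("all design counts must be >= 1")
  if (cfg$n_token_types > 8L) .stop_data("at most 8 token types")
  if (!all(cfg$rates %in% 3:7)) .stop_data("rates must lie in 3..7")
  structure(cfg, class = "cohort_config")
}

## analytic sensor paths for one token; returns named list of N x 2
## matrices over the time vector t (seconds), given token parameters.
## Exposed internally so tests can compare noiseless output to the curves.
.synth_paths <- function(t, v1, dur, f1_rel, f2_rel, amp, x_targets,
                         loop_amp = 0, effort_centre = NA, effort_amp = 0,
                         effort_freq = 6) {
  tau <- pmin(pmax((t - v1) / dur, 0), 1)
  ## tongue tip: posture transitions + two palate-directed excursions
  x <- x_targets[1L] +
    (x_targets[2L] - x_targets[1L]) * .rc_step(tau, f1_rel, 0.25) +
    (x_targets[3L] - x_targets[2L]) * .rc_step(tau, f2_rel, 0.25)
  y <- -8 + amp * (.rc_pulse(tau, f1_rel, 0.22) + .rc_pulse(tau, f2_rel, 0.22))
  if (loop_amp > 0) {
    ## categorically different slow gait: added loop between the flaps,
    ## leaving the effort-placement windows at token edges untouched
    mid <- (f1_rel + f2_rel) / 2
    phi <- pmin(pmax((tau - (mid - 0.15)) / 0.3, 0), 1)
    x <- x + loop_amp * sin(2 * pi * phi)
    y <- y + 0.5 * loop_amp * (1 - cos(2 * pi * phi))
  }
  if (effort_amp > 0 && is.finite(effort_centre)) {
    env <- .rc_pulse(tau, effort_centre, 0.28)
    y <- y + effort_amp * env * cos(2 * pi * effort_freq * tau)
    x <- x + 0.5 * effort_amp * env * sin(2 * pi * effort_freq * tau)
  }
  tt <- cbind(x, y)
  ctr <- c(x_targets[2L], -8)
  scale_copy <- function(k, shift) {
    sweep(sweep(tt, 2L, ctr) * k, 2L, ctr + shift, "+")
  }
  list(
    TT = tt,
    TB = scale_copy(0.65, c(-12, -1)),
    TD = scale_copy(0.35, c(-24, -2)),
    LI = cbind(x_targets[2L] + 6 + 0 * tau,
               -20 - 1.5 * (.rc_pulse(tau, f1_rel, 0.2) +
                              .rc_pulse(tau, f2_rel, 0.2))),
    UL = cbind(x_targets[2L] + 18 + 0.3 * .rc_pulse(tau, 0.5, 0.5),
               2 + 0 * tau),
    LL = cbind(x_targets[2L] + 16 + 0 * tau,
               -10 - 0.8 * (.rc_pulse(tau, f1_rel, 0.25) +
                              .rc_pulse(tau, f2_rel, 0.25)))
  )
}

## deterministic token-type geometry: posture targets and a range multiplier
.token_type_params <- function(n_token_types) {
  i <- seq_len(n_token_types)
  list(x_targets = lapply(i, function(k)
         30 + c(3, 0, -3) + 1.5 * sin(2 * pi * k / 8 + c(0, 2, 4))),
       range_mult = if (n_token_types == 1L) 1
                    else seq(0.85, 1.15, length.out = n_token_types))
}

#' Generate a synthetic cohort
#'
#' Builds one [token_recording] per participant x token type x rate x block
#' under the programmed speaker profiles, together with a ground-truth table
#' of every programmed quantity. Deterministic given `cfg$seed`.
#'
#' Programmed structure: flap-excursion amplitude grows at slower prompts in
#' proportion to the speaker x token-type range `base_range * range_mult`
#' (so recovered displacement range tracks the programmed one); token
#' duration shrinks with prompt rate, with a duration range that widens with
#' `base_range` (negative displacement-range x rate interaction on
#' duration); two-gait speakers add a path loop below the rate threshold;
#' the effort wiggle sits early for `end_state_comfort` speakers and over
#' the second flap for `mid_token_effort` speakers.
#'
#' @param cfg A [cohort_config].
#' @param profiles Data frame from [speaker_profiles()]; must match
#'   `cfg$n_participants`.
#' @return List with `recordings` (named list of [token_recording]), `truth`
#'   (data frame of programmed quantities per token), `profiles`, `config`.
#' @export
make_cohort <- function(cfg = cohort_config(),
                        profiles = speaker_profiles(cfg$n_participants)) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (nrow(profiles) != cfg$n_participants)
    .stop_data("profiles rows (", nrow(profiles),
               ") != n_participants (", cfg$n_participants, ")")
  ttp <- .token_type_params(cfg$n_token_types)
  dt <- 1 / cfg$sample_rate
  pad <- 0.15
  d_fast0 <- 3 / 7          # three syllables at the fastest prompt
  amp0 <- 6                 # baseline flap excursion, mm
  amp_slope <- 2.2          # extra slow-rate amplitude per unit range
  recordings <- list()
  truth <- vector("list",
                  cfg$n_participants * cfg$n_token_types *
                    length(cfg$rates) * cfg$n_blocks)
  ti <- 0L
  with_seed(cfg$seed, {
    for (pi in seq_len(cfg$n_participants)) {
      prof <- profiles[pi, ]
      d_fast <- d_fast0 * exp(stats::rnorm(1L, 0, 0.05))
      for (tt in seq_len(cfg$n_token_types)) {
        cell_range <- prof$base_range * ttp$range_mult[tt]
        dur_range <- 0.08 + prof$duration_range_slope * cell_range
        for (rate in cfg$rates) for (blk in seq_len(cfg$n_blocks)) {
          dur <- d_fast + dur_range * (7 - rate) / 4 +
            stats::rnorm(1L, 0, 0.025)
          dur <- max(dur, 0.2)
          v1 <- pad
          f1_rel <- 0.35 + stats::runif(1L, -0.02, 0.02)
          f2_rel <- 0.68 + stats::runif(1L, -0.02, 0.02)
          amp <- amp0 + amp_slope * cell_range * (7 - rate) / 4
          loop <- prof$gait_count == 2L && rate < cfg$gait_rate_threshold
          eff_c <- if (prof$esc_profile == "end_state_comfort") 0.12
                   else f2_rel
          ## effort wiggle scales with excursion size: effort-related motor
          ## noise is proportional to movement amplitude
          eff_amp <- cfg$effort_amp * amp / amp0
          t <- seq(0, v1 + dur + pad, by = dt)
          paths <- .synth_paths(t, v1, dur, f1_rel, f2_rel, amp,
                                ttp$x_targets[[tt]],
                                loop_amp = if (loop) 3 else 0,
                                effort_centre = eff_c,
                                effort_amp = eff_amp)
          trajs <- list()
          for (s in SENSOR_IDS) {
            pos <- paths[[s]] +
              matrix(stats::rnorm(2L * length(t), 0, cfg$noise_sd),
                     ncol = 2L)
            valid <- rep(TRUE, length(t))
            if (cfg$dropout_prob > 0 &&
                stats::runif(1L) < cfg$dropout_prob) {
              len <- sample.int(cfg$dropout_max, 1L)
              if (length(t) > len + 4L) {
                at <- sample.int(length(t) - len - 2L, 1L) + 1L
                valid[at:(at + len - 1L)] <- FALSE
                pos[!valid, ] <- NA_real_
              }
            }
            trajs[[s]] <- sensor_trajectory(s, t, pos, valid)
          }
          lm <- landmark_set(v1, v1 + f1_rel * dur, v1 + f2_rel * dur,
                             v1 + dur)
          rec <- token_recording(prof$participant, tt, blk, rate, trajs, lm)
          recordings[[token_key(rec)]] <- rec
          ti <- ti + 1L
          truth[[ti]] <- data.frame(
            participant = prof$participant, token_type = tt, block = blk,
            rate = rate, duration = dur, base_range = prof$base_range,
            range_mult = ttp$range_mult[tt], cell_range = cell_range,
            programmed_amp_range = amp_slope * cell_range,
            duration_range = dur_range, amp = amp,
            esc_profile = prof$esc_profile, gait_count = prof$gait_count,
            loop_used = loop, stringsAsFactors = FALSE)
        }
      }
    }
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(recordings = recordings, truth = truth, profiles = profiles,
       config = cfg)
}

#' Compare programmed truth against pipeline recoveries
#'
#' Pairs the generator's ground-truth table with pipeline outputs:
#' programmed vs recovered tongue-front displacement range (Spearman rank
#' correlation and sign agreement), programmed vs realized duration range,
#' and effort placement (mean early-window minus late-window tongue-front
#' fluctuation per cell, summarized by programmed profile).
#'
#' @param truth Ground-truth table from [make_cohort()].
#' @param ranges Output of [displacement_range()] (tongue-front rows used).
#' @param t_table Per-token displacement table (for realized durations);
#'   optional.
#' @param fluct Output of [fluctuation_table()]; optional.
#' @return An object of class `recovery_report`: list of comparison tables
#'   and summary statistics.
#' @export
programmed_vs_recovered <- function(truth, ranges, t_table = NULL,
                                    fluct = NULL) {
  rg <- ranges[ranges$sensor_set == "tongue_front" & !ranges$absent, ]
  cell <- unique(truth[, c("participant", "token_type",
                           "programmed_amp_range", "duration_range",
                           "esc_profile")])
  key_c <- paste(cell$participant, cell$token_type, sep = ".")
  key_r <- paste(rg$participant, rg$token_type, sep = ".")
  idx <- match(key_c, key_r)
  if (anyNA(idx))
    .stop_data("alignment error: no recovered range for cell(s) ",
               paste(utils::head(key_c[is.na(idx)], 3L), collapse = ", "))
  disp <- data.frame(cell[, c("participant", "token_type")],
                     programmed = cell$programmed_amp_range,
                     recovered = rg$range_value[idx])
  out <- list(displacement = disp,
              rank_correlation = stats::cor(disp$programmed, disp$recovered,
                                            method = "spearman"),
              sign_agreement = mean(sign(disp$recovered) ==
                                      sign(disp$programmed)))
  if (!is.null(t_table)) {
    if (!is.null(t_table$sensor_set))
      t_table <- t_table[t_table$sensor_set == t_table$sensor_set[1L], ]
    dr <- displacement_range(transform(t_table, T = duration))
    idx2 <- match(key_c, paste(dr$participant, dr$token_type, sep = "."))
    dur <- data.frame(cell[, c("participant", "token_type")],
                      programmed = cell$duration_range,
                      recovered = dr$range_value[idx2])
    dur <- dur[!is.na(dur$recovered), ]
    out$duration <- dur
    out$duration_correlation <- stats::cor(dur$programmed, dur$recovered)
  }
  if (!is.null(fluct)) {
    early <- fluct$fts_index <= 7L
    late <- fluct$fts_index >= 17L
    kf <- paste(fluct$participant, fluct$token_type, sep = ".")
    contrast <- vapply(key_c, function(k)
      mean(fluct$F_front[kf == k & early]) -
        mean(fluct$F_front[kf == k & late]), numeric(1))
    fl <- data.frame(cell[, c("participant", "token_type", "esc_profile")],
                     early_minus_late = unname(contrast))
    out$fluctuation <- fl
    out$esc_positive_rate <-
      mean(fl$early_minus_late[fl$esc_profile == "end_state_comfort"] > 0)
    out$mid_negative_rate <-
      mean(fl$early_minus_late[fl$esc_profile == "mid_token_effort"] < 0)
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  displacement range: rank correlation %.3f, sign agreement %.2f (n = %d cells)\n",
              x$rank_correlation, x$sign_agreement, nrow(x$displacement)))
  if (!is.null(x$duration_correlation))
    cat(sprintf("  duration range: correlation %.3f\n", x$duration_correlation))
  if (!is.null(x$esc_positive_rate))
    cat(sprintf("  effort placement: early>late in %.0f%% of end-state-comfort cells, late>early in %.0f%% of mid-token cells\n",
                100 * x$esc_positive_rate, 100 * x$mid_negative_rate))
  invisible(x)
}
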