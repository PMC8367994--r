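# Fixtures are built in code; nothing is read from disk except what a test
# itself writes to tempdir().

# A hand-built token with analytic sensor paths: TT follows a sine arc, TB a
# shifted copy, sampled at 100 Hz over [0, t_end].
make_test_recording <- function(participant = "P01", token_type = 1L,
                                block = 1L, rate = 5L,
                                t_end = 0.8, lm = c(0.1, 0.3, 0.5, 0.7)) {
  t <- seq(0, t_end, by = 0.01)
  tt <- sensor_trajectory("TT", t, cbind(30 + 10 * t, -8 + 3 * sin(2 * pi * t)))
  tb <- sensor_trajectory("TB", t, cbind(18 + 8 * t, -9 + 2 * sin(2 * pi * t)))
  token_recording(participant, token_type, block, rate,
                  list(TT = tt, TB = tb),
                  landmark_set(lm[1], lm[2], lm[3], lm[4]))
}

# random 31 x 2 path with step scale `scale` (mm)
random_path <- function(scale = 2) {
  apply(matrix(rnorm(31 * 2, sd = scale), ncol = 2), 2, cumsum)
}

# small cohort used across tests
tiny_cohort <- function(seed = 42, n_participants = 2, n_token_types = 2,
                        n_blocks = 1, ...) {
  make_cohort(cohort_config(n_participants = n_participants,
                            n_token_types = n_token_types,
                            n_blocks = n_blocks, seed = seed, ...))
}

# independent transcription of the integer-grid fluctuation formula
# (points of return -> monotone periods; |dx| / (index extent), normalized
# by s * (m - 1)); deliberately written without reusing package internals.
schiepek_window_F <- function(x, s = 2 * pi) {
  m <- length(x)
  d <- diff(x)
  dir <- sign(d)
  # resolve plateaus: carry previous nonzero direction, leading plateaus
  # take the first nonzero direction
  nz <- which(dir != 0)
  if (length(nz) == 0) return(0)
  dir[seq_len(nz[1] - 1)] <- dir[nz[1]]
  for (i in seq_along(dir)[-1]) if (dir[i] == 0) dir[i] <- dir[i - 1]
  bounds <- c(1, which(diff(dir) != 0) + 1, m)
  total <- 0
  for (j in seq_len(length(bounds) - 1)) {
    a <- bounds[j]; b <- bounds[j + 1]
    total <- total + abs(x[b] - x[a]) / (b - a)
  }
  total / (s * (m - 1))
}

# brute-force unsigned turning angle accumulation via acos (independent of
# the atan2-based implementation)
brute_theta <- function(path) {
  tot <- 0
  for (i in 1:29) {
    a <- path[i + 1, ] - path[i, ]
    b <- path[i + 2, ] - path[i + 1, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na < 1e-12 || nb < 1e-12) next
    cosang <- max(-1, min(1, sum(a * b) / (na * nb)))
    tot <- tot + acos(cosang)
  }
  tot
}
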