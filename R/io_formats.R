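## io_formats: external representations and validated in-memory objects.
##
## Canonical on-disk trajectory format is long/tidy delimited text, one row
## per sensor sample, with header
##   participant,token_type,block,rate,sensor,time_s,x_mm,y_mm,valid
## Landmarks travel either as extra columns of that table, as a separate
## 4-column delimited file, or as a Praat TextGrid with a three-tier layout
## (phrase intervals keyed by token, a vowel-flap-vowel sequence interval,
## and a point tier with the two flap intensity minima).

#' Construct a sensor trajectory
#'
#' A single EMA coil's midsagittal trajectory: strictly increasing sample
#' times (seconds, nominal 100 Hz), an N x 2 position matrix (millimetres,
#' x anterior-positive, y superior-positive) and a per-sample validity mask
#' (`FALSE` marks dropouts / missing samples).
#'
#' @param sensor_id One of [SENSOR_IDS].
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param positions Numeric matrix with `length(times)` rows and 2 columns
#'   (x, y) in millimetres. May contain `NA` where `valid` is `FALSE`.
#' @param valid Logical vector, one entry per sample; defaults to all valid.
#' @return An object of class `sensor_trajectory`.
#' @export
sensor_trajectory <- function(sensor_id, times, positions,
                              valid = rep(TRUE, length(times))) {
  sensor_id <- as.character(sensor_id)
  if (!sensor_id %in% SENSOR_IDS)
    .stop_data("unknown sensor id '", sensor_id, "'")
  times <- as.numeric(times)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  valid <- as.logical(valid)
  if (ncol(positions) != 2L)
    .stop_data("positions must have 2 columns (x_mm, y_mm)")
  if (nrow(positions) != length(times) || length(valid) != length(times))
    .stop_data("times, positions and valid_mask lengths differ for sensor ",
               sensor_id)
  if (length(times) > 1L && any(diff(times) <= 0))
    .stop_data("times not strictly increasing for sensor ", sensor_id)
  if (any(!is.finite(positions[valid, , drop = FALSE])))
    .stop_data("non-finite position marked valid for sensor ", sensor_id)
  structure(list(sensor_id = sensor_id, times = times,
                 positions = positions, valid = valid),
            class = "sensor_trajectory")
}

#' Construct a landmark set
#'
#' The four acoustic landmark times anchoring the Procrustean fit: onset of
#' the first vowel, intensity minima of the two flaps, and end of the third
#' vowel. Strictly increasing, seconds on the recording's time base.
#'
#' @param v1_onset,flap1_min,flap2_min,v3_end Landmark times in seconds.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(v1_onset, flap1_min, flap2_min, v3_end) {
  lm <- c(v1_onset = as.numeric(v1_onset), flap1_min = as.numeric(flap1_min),
          flap2_min = as.numeric(flap2_min), v3_end = as.numeric(v3_end))
  if (any(!is.finite(lm)))
    .stop_data("landmark times must be finite")
  if (any(diff(lm) <= 0))
    .stop_data("landmarks must satisfy v1_onset < flap1_min < flap2_min < v3_end; got (",
               paste(signif(lm, 8), collapse = ", "), ")")
  structure(as.list(lm), class = "landmark_set")
}

#' Construct a token recording
#'
#' One token utterance: per-sensor trajectories, the four landmark times and
#' the experimental metadata. Tongue tip and tongue body trajectories are
#' required because all downstream tongue-front measures depend on them;
#' landmark times must fall inside every trajectory's time span.
#'
#' @param participant Participant identifier (coerced to character).
#' @param token_type Integer token type, 1 to 8.
#' @param block Integer recording block, 1 to 10.
#' @param rate Reiterant prompt rate in syllables/second, one of 3:7.
#' @param trajectories Named list of [sensor_trajectory] objects (names are
#'   sensor ids).
#' @param landmarks A [landmark_set].
#' @return An object of class `token_recording`.
#' @export
token_recording <- function(participant, token_type, block, rate,
                            trajectories, landmarks) {
  token_type <- as.integer(token_type)
  block <- as.integer(block)
  rate <- as.integer(rate)
  if (is.na(token_type) || token_type < 1L || token_type > 8L)
    .stop_data("token_type must be an integer in 1..8")
  if (is.na(block) || block < 1L || block > 10L)
    .stop_data("block must be an integer in 1..10")
  if (is.na(rate) || !rate %in% 3:7)
    .stop_data("reiterant rate must be one of 3,4,5,6,7 syllables/s")
  if (!inherits(landmarks, "landmark_set"))
    .stop_data("landmarks must be a landmark_set")
  if (!is.list(trajectories) || length(trajectories) == 0L)
    .stop_data("trajectories must be a non-empty named list")
  ids <- vapply(trajectories, function(tr) tr$sensor_id, character(1))
  names(trajectories) <- ids
  if (anyDuplicated(ids))
    .stop_data("duplicate sensor trajectories: ",
               paste(ids[duplicated(ids)], collapse = ", "))
  if (!all(c("TT", "TB") %in% ids))
    .stop_data("token requires at least TT and TB sensors; has ",
               paste(ids, collapse = ", "))
  span <- vapply(trajectories, function(tr) range(tr$times), numeric(2))
  lo <- max(span[1, ]); hi <- min(span[2, ])
  lmv <- unlist(landmarks)
  if (any(lmv < lo - 1e-9) || any(lmv > hi + 1e-9))
    .stop_data("landmark times fall outside trajectory time span [",
               signif(lo, 6), ", ", signif(hi, 6), "]")
  structure(list(participant = as.character(participant),
                 token_type = token_type, block = block, rate = rate,
                 trajectories = trajectories, landmarks = landmarks),
            class = "token_recording")
}

#' Token key
#'
#' Canonical unique key for a token: `participant.token_type.block.rate`.
#'
#' @param rec A [token_recording], or a participant id when the remaining
#'   fields are supplied.
#' @param token_type,block,rate Metadata fields when `rec` is a participant
#'   id.
#' @return Character key.
#' @export
token_key <- function(rec, token_type = NULL, block = NULL, rate = NULL) {
  if (inherits(rec, "token_recording"))
    paste(rec$participant, rec$token_type, rec$block, rec$rate, sep = ".")
  else paste(rec, token_type, block, rate, sep = ".")
}

#' @export
print.token_recording <- function(x, ...) {
  cat("<token_recording>", token_key(x), "sensors:",
      paste(names(x$trajectories), collapse = ","),
      sprintf("duration %.3f s\n", x$landmarks$v3_end - x$landmarks$v1_onset))
  invisible(x)
}

.traj_cols <- c("participant", "token_type", "block", "rate",
                "sensor", "time_s", "x_mm", "y_mm", "valid")
.lm_cols <- c("v1_onset", "flap1_min", "flap2_min", "v3_end")

.read_delim_auto <- function(path) {
  if (!file.exists(path)) .stop_data("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a tidy trajectory table into token recordings
#'
#' Reads the canonical long trajectory format (CSV or TSV; one row per
#' sensor sample) and assembles one validated [token_recording] per
#' `(participant, token_type, block, rate)` group. Landmarks may be present
#' as constant per-group columns `v1_onset, flap1_min, flap2_min, v3_end`,
#' or supplied separately via `landmarks`.
#'
#' @param path Path to the delimited file.
#' @param landmarks Optional landmark source: a path passed to
#'   [read_landmarks()], or a named list of [landmark_set] keyed by
#'   [token_key()].
#' @return Named list of [token_recording] objects, keyed by [token_key()].
#' @export
read_trajectory_table <- function(path, landmarks = NULL) {
  df <- .read_delim_auto(path)
  missing_cols <- setdiff(.traj_cols, names(df))
  if (length(missing_cols))
    .stop_data("trajectory table missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  has_lm_cols <- all(.lm_cols %in% names(df))
  if (!has_lm_cols && is.null(landmarks))
    .stop_data("no landmark columns in table and no landmark source given")
  recordings_from_table(df, landmarks = landmarks)
}

#' Assemble token recordings from a long data frame
#'
#' In-memory equivalent of [read_trajectory_table()]: takes a data frame in
#' the canonical long format and returns validated recordings.
#'
#' @param df Data frame with the canonical columns (see
#'   [read_trajectory_table()]).
#' @param landmarks Optional named list of [landmark_set] keyed by
#'   [token_key()]; used when `df` lacks landmark columns.
#' @return Named list of [token_recording] objects.
#' @export
recordings_from_table <- function(df, landmarks = NULL) {
  key <- paste(df$participant, df$token_type, df$block, df$rate, sep = ".")
  out <- list()
  for (k in unique(key)) {
    g <- df[key == k, , drop = FALSE]
    trajs <- list()
    for (s in unique(g$sensor)) {
      gs <- g[g$sensor == s, , drop = FALSE]
      ord <- order(gs$time_s)
      gs <- gs[ord, , drop = FALSE]
      if (anyDuplicated(gs$time_s))
        .stop_data("duplicate sample times for sensor ", s, " in token ", k)
      tr <- try(sensor_trajectory(s, gs$time_s,
                                  cbind(gs$x_mm, gs$y_mm),
                                  as.logical(gs$valid)), silent = TRUE)
      if (inherits(tr, "try-error"))
        .stop_data("invalid trajectory for sensor ", s, " in token ", k,
                   ": ", attr(tr, "condition")$message)
      trajs[[s]] <- tr
    }
    lm <- if (!is.null(landmarks)) {
      if (is.null(landmarks[[k]]))
        .stop_data("no landmarks found for token ", k)
      landmarks[[k]]
    } else {
      lr <- g[1L, .lm_cols]
      landmark_set(lr$v1_onset, lr$flap1_min, lr$flap2_min, lr$v3_end)
    }
    g1 <- g[1L, ]
    out[[k]] <- token_recording(g1$participant, g1$token_type, g1$block,
                                g1$rate, trajs, lm)
  }
  out
}

#' Flatten token recordings to the canonical long table
#'
#' Inverse of [recordings_from_table()]; landmark times are repeated as
#' per-row columns so a single file round-trips the full object.
#'
#' @param recs List of [token_recording] objects.
#' @return Data frame in the canonical long format with landmark columns.
#' @export
recordings_to_table <- function(recs) {
  rows <- lapply(recs, function(rec) {
    lm <- rec$landmarks
    do.call(rbind, lapply(rec$trajectories, function(tr) {
      data.frame(participant = rec$participant, token_type = rec$token_type,
                 block = rec$block, rate = rec$rate, sensor = tr$sensor_id,
                 time_s = tr$times, x_mm = tr$positions[, 1],
                 y_mm = tr$positions[, 2], valid = tr$valid,
                 v1_onset = lm$v1_onset, flap1_min = lm$flap1_min,
                 flap2_min = lm$flap2_min, v3_end = lm$v3_end,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write token recordings as a tidy trajectory table
#'
#' @param recs List of [token_recording] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(recs, path) {
  df <- recordings_to_table(recs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark annotations
#'
#' Accepts two dialects and normalizes both to named [landmark_set] objects:
#' \itemize{
#'   \item delimited text (CSV/TSV) with key columns `participant,
#'     token_type, block, rate` (or a single `token` column) and the four
#'     landmark columns `v1_onset, flap1_min, flap2_min, v3_end`;
#'   \item a Praat long-format TextGrid with a phrase interval tier whose
#'     labels are token keys, a sequence interval tier whose labelled
#'     interval bounds give first-vowel onset and third-vowel end, and a
#'     point tier carrying the two flap intensity minima.
#' }
#'
#' @param path Path to the annotation file.
#' @return Named list of [landmark_set], keyed by [token_key()] (or by the
#'   `token` column for the generic delimited dialect).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) .stop_data("file not found: ", path)
  head1 <- readLines(path, n = 2L, warn = FALSE)
  if (any(grepl("ooTextFile|TextGrid", head1)))
    return(.read_landmarks_textgrid(path))
  df <- .read_delim_auto(path)
  missing_cols <- setdiff(.lm_cols, names(df))
  if (length(missing_cols))
    .stop_data("landmark file missing column(s): ",
               paste(missing_cols, collapse = ", "))
  keys <- if ("token" %in% names(df)) as.character(df$token)
          else if (all(c("participant", "token_type", "block", "rate") %in% names(df)))
            paste(df$participant, df$token_type, df$block, df$rate, sep = ".")
          else .stop_data("landmark file needs a 'token' column or the four key columns")
  if (anyDuplicated(keys))
    .stop_data("duplicate landmark rows for token(s): ",
               paste(unique(keys[duplicated(keys)]), collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i)
    landmark_set(df$v1_onset[i], df$flap1_min[i], df$flap2_min[i],
                 df$v3_end[i]))
  names(out) <- keys
  out
}

## Minimal long-format TextGrid reader: returns list of tiers, each a list
## with $name, $type ("interval"/"point") and a data.frame of marks.
.parse_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  txt <- function(l) gsub("^\\s*\\S+\\s*=\\s*\"(.*)\"\\s*$", "\\1", l)
  tiers <- list()
  i <- 1L; n <- length(lines)
  tier_start <- function(l) grepl("class\\s*=\\s*\"(IntervalTier|TextTier)\"", l)
  while (i <= n) {
    l <- lines[i]
    if (tier_start(l)) {
      type <- if (grepl("IntervalTier", l)) "interval" else "point"
      name <- txt(lines[i + 1L])
      i <- i + 1L
      rows <- list()
      while (i <= n && !tier_start(lines[i])) {
        li <- lines[i]
        if (type == "interval" && grepl("xmin\\s*=", li) &&
            grepl("xmax\\s*=", lines[i + 1L]) && grepl("text\\s*=", lines[i + 2L])) {
          rows[[length(rows) + 1L]] <-
            data.frame(xmin = num(li), xmax = num(lines[i + 1L]),
                       text = txt(lines[i + 2L]), stringsAsFactors = FALSE)
          i <- i + 3L
        } else if (type == "point" && grepl("(number|time)\\s*=", li) &&
                   grepl("(mark|text)\\s*=", lines[i + 1L])) {
          rows[[length(rows) + 1L]] <-
            data.frame(time = num(li), mark = txt(lines[i + 1L]),
                       stringsAsFactors = FALSE)
          i <- i + 2L
        } else i <- i + 1L
      }
      tiers[[length(tiers) + 1L]] <-
        list(name = name, type = type,
             marks = if (length(rows)) do.call(rbind, rows) else NULL)
    } else i <- i + 1L
  }
  tiers
}

.read_landmarks_textgrid <- function(path) {
  tiers <- .parse_textgrid(path)
  itypes <- vapply(tiers, `[[`, character(1), "type")
  ints <- which(itypes == "interval")
  pts <- which(itypes == "point")
  if (length(ints) < 2L || length(pts) < 1L)
    .stop_data("TextGrid must contain two interval tiers (phrase, sequence) ",
               "and a point tier (flaps): found ", length(ints),
               " interval and ", length(pts), " point tier(s)")
  phrase <- tiers[[ints[1L]]]$marks
  seqs <- tiers[[ints[2L]]]$marks
  flaps <- tiers[[pts[1L]]]$marks
  phrase <- phrase[nzchar(trimws(phrase$text)), , drop = FALSE]
  seqs <- seqs[nzchar(trimws(seqs$text)), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(phrase))) {
    key <- trimws(phrase$text[i])
    inside <- seqs$xmin >= phrase$xmin[i] - 1e-9 &
      seqs$xmax <= phrase$xmax[i] + 1e-9
    if (sum(inside) != 1L)
      .stop_data("expected exactly one sequence interval inside phrase '",
                 key, "', found ", sum(inside))
    sq <- seqs[inside, ]
    fl <- sort(flaps$time[flaps$time > sq$xmin & flaps$time < sq$xmax])
    if (length(fl) != 2L)
      .stop_data("expected two flap points inside sequence of '", key,
                 "', found ", length(fl))
    out[[key]] <- landmark_set(sq$xmin, fl[1L], fl[2L], sq$xmax)
  }
  out
}

#' Write a TextGrid landmark file
#'
#' Emits the three-tier layout consumed by [read_landmarks()]: a phrase
#' interval tier labelled with token keys, a sequence interval tier spanning
#' first-vowel onset to third-vowel end, and a flap point tier.
#'
#' @param landmarks Named list of [landmark_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks_textgrid <- function(landmarks, path) {
  keys <- names(landmarks)
  v1 <- vapply(landmarks, `[[`, numeric(1), "v1_onset")
  v3 <- vapply(landmarks, `[[`, numeric(1), "v3_end")
  xmax <- max(v3) + 0.1
  fmt <- function(x) sprintf("%.10g", x)
  con <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
           "xmin = 0", paste0("xmax = ", fmt(xmax)),
           "tiers? <exists>", "size = 3", "item []:")
  int_tier <- function(name, xmin_v, xmax_v, labels) {
    c(paste0("    item:"),
      '        class = "IntervalTier"',
      paste0('        name = "', name, '"'),
      "        xmin = 0", paste0("        xmax = ", fmt(xmax)),
      paste0("        intervals: size = ", length(labels)),
      unlist(lapply(seq_along(labels), function(i)
        c(paste0("        intervals [", i, "]:"),
          paste0("            xmin = ", fmt(xmin_v[i])),
          paste0("            xmax = ", fmt(xmax_v[i])),
          paste0('            text = "', labels[i], '"')))))
  }
  flap_t <- sort(unlist(lapply(landmarks, function(l)
    c(l$flap1_min, l$flap2_min))))
  pt_tier <- c("    item:", '        class = "TextTier"',
               '        name = "flaps"',
               "        xmin = 0", paste0("        xmax = ", fmt(xmax)),
               paste0("        points: size = ", length(flap_t)),
               unlist(lapply(seq_along(flap_t), function(i)
                 c(paste0("        points [", i, "]:"),
                   paste0("            number = ", fmt(flap_t[i])),
                   '            mark = "flap"'))))
  lines <- c(con,
             int_tier("phrase", pmax(v1 - 0.05, 0), v3 + 0.05, keys),
             int_tier("sequence", v1, v3, keys),
             pt_tier)
  writeLines(lines, path)
  invisible(path)
}

#' Write result tables with a manifest
#'
#' Writes each table as CSV with stable column order and emits
#' `MANIFEST.txt` listing every file with its MD5 content hash. Output is
#' byte-deterministic given identical inputs.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (!is.list(tables) || is.null(names(tables)) || any(!nzchar(names(tables))))
    .stop_data("tables must be a named list of data frames")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    .stop_data("cannot write to directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, eol = "\n")
    paths <- c(paths, p)
  }
  hashes <- tools::md5sum(paths)
  manifest <- file.path(out_dir, "MANIFEST.txt")
  writeLines(paste(basename(paths), unname(hashes), sep = "\t"), manifest)
  invisible(c(paths, manifest))
}
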