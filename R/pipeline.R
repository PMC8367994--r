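## pipeline: end-to-end orchestration. Stages communicate via on-disk tables
## so any stage can be rerun or inspected in isolation; a run record
## (resolved config, package version, input hashes) is written alongside the
## outputs, and outputs are pure functions of (inputs, config, seed).

#' Build a run configuration
#'
#' Either a synthetic run (a [cohort_config()] plus optional profile
#' settings) or a data run (paths to a trajectory table and, if needed, a
#' landmark file). Accepts a YAML file path or an R list.
#'
#' @param x Path to a YAML config file, or a list; `NULL` (default) yields a
#'   synthetic run with default settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(x = NULL) {
  cfg <- if (is.null(x)) list()
         else if (is.character(x)) yaml::read_yaml(x)
         else if (is.list(x)) x
         else .stop_data("config must be a path, a list, or NULL")
  defaults <- list(
    synthetic = list(enabled = TRUE),
    input = list(trajectories = NULL, landmarks = NULL),
    smoother = list(lambda = "auto", max_gap = 20L),
    palate = list(bin_mm = 1, mad_k = 3),
    sensors = SENSOR_IDS,
    model = list(aggregate = "cell_mean", k_te = c(8, 5), k_fs = 5),
    seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      for (k in names(defaults[[nm]]))
        if (is.null(cfg[[nm]][[k]])) cfg[[nm]][[k]] <- defaults[[nm]][[k]]
  }
  structure(cfg, class = "run_config")
}

.stage <- function(out_dir, name, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(c(paste("stage:", name), paste("error:", conditionMessage(e))),
               file.path(out_dir, "FAILED"))
    .stop_data("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic or user data: acquisition,
#' smoothing/alignment, palate estimation, Procrustean resampling,
#' displacement metrics and ranges (all sensor-set variants present),
#' fluctuation series, the duration GLMM with the four-variant comparison,
#' the fluctuation GAMM, and (when ground truth exists) the
#' programmed-vs-recovered report. Stage outputs are written as CSV tables
#' with a hash manifest, plus QC plots and a JSON run record. A stage error
#' aborts the run, leaving partial outputs and a `FAILED` marker naming the
#' stage.
#'
#' @param cfg A [run_config()] (or anything it accepts).
#' @param out_dir Output directory.
#' @param qc_plots Emit QC PNGs (a per-token trace plot and the
#'   displacement-range vs duration scatter); default `TRUE`.
#' @return Invisibly, a list with the main in-memory results (`ranges`,
#'   `fluctuation`, `glmm`, `comparison`, `gamm`, `recovery`, `out_dir`).
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, qc_plots = TRUE) {
  cfg <- run_config(unclass(cfg))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .stop_data("cannot create output directory: ", out_dir)
  acq <- .stage(out_dir, "acquire", {
    if (isTRUE(cfg$synthetic$enabled)) {
      syn <- cfg$synthetic
      syn$enabled <- NULL
      prof_args <- syn$profiles; syn$profiles <- NULL
      ccfg <- do.call(cohort_config,
                      c(syn[setdiff(names(syn), "seed")],
                        list(seed = cfg$seed)))
      profiles <- if (is.null(prof_args)) speaker_profiles(ccfg$n_participants)
                  else do.call(speaker_profiles,
                               c(list(n_participants = ccfg$n_participants),
                                 prof_args))
      cohort <- make_cohort(ccfg, profiles)
      list(recs = cohort$recordings, truth = cohort$truth, hashes = NULL)
    } else {
      paths <- c(cfg$input$trajectories, cfg$input$landmarks)
      list(recs = read_trajectory_table(cfg$input$trajectories,
                                        landmarks = cfg$input$landmarks),
           truth = NULL, hashes = as.list(tools::md5sum(paths)))
    }
  })
  recs <- acq$recs
  truth <- acq$truth
  input_hashes <- acq$hashes
  smoother <- smoother_config(cfg$smoother$lambda, cfg$smoother$max_gap)
  pre <- .stage(out_dir, "preprocess", {
    lapply(recs, preprocess_recording, cfg = smoother,
           sensors = cfg$sensors)
  })
  palate <- .stage(out_dir, "palate",
                   estimate_palate(pre, bin_mm = cfg$palate$bin_mm,
                                   mad_k = cfg$palate$mad_k))
  ptokens <- .stage(out_dir, "normalize", lapply(pre, resample_token))
  disp <- .stage(out_dir, "displacement", {
    metrics <- path_metrics(ptokens)
    summary <- displacement_summary(metrics)
    list(metrics = metrics, summary = summary,
         ranges = displacement_range(summary))
  })
  fluct <- .stage(out_dir, "fluctuation", fluctuation_table(ptokens))
  models <- .stage(out_dir, "model", {
    variants <- intersect(unique(disp$ranges$sensor_set),
                          names(DISPLACEMENT_SENSOR_SETS))
    frames <- lapply(variants, function(v)
      duration_model_frame(disp$summary, disp$ranges, sensor_set = v,
                           aggregate = cfg$model$aggregate))
    names(frames) <- variants
    glmm <- fit_duration_glmm(frames[["tongue_front"]])
    comparison <- if (length(frames) >= 2L)
      compare_displacement_models(frames) else NULL
    gframe <- fluctuation_model_frame(fluct, disp$ranges)
    gamm <- fit_fluctuation_gamm(gframe, k_te = cfg$model$k_te,
                                 k_fs = cfg$model$k_fs)
    list(glmm = glmm, comparison = comparison, gamm = gamm)
  })
  recovery <- if (!is.null(truth))
    .stage(out_dir, "recover",
           programmed_vs_recovered(truth, disp$ranges,
                                   t_table = disp$summary, fluct = fluct))
  tables <- list(
    procrustean = procrustean_table(ptokens),
    palate = palate,
    path_metrics = disp$metrics,
    displacement = disp$summary,
    displacement_range = disp$ranges,
    fluctuation = fluct,
    glmm_coefficients = cbind(term = rownames(models$glmm$coefficients),
                              models$glmm$coefficients),
    gamm_smooths = cbind(term = rownames(models$gamm$smooth_table),
                         models$gamm$smooth_table))
  if (!is.null(models$comparison))
    tables$model_comparison <- models$comparison
  if (!is.null(recovery)) {
    tables$recovery_displacement <- recovery$displacement
    if (!is.null(recovery$fluctuation))
      tables$recovery_fluctuation <- recovery$fluctuation
  }
  if (!is.null(truth)) tables$ground_truth <- truth
  .stage(out_dir, "write", write_results(tables, out_dir))
  sidecar <- list(
    glmm = list(r2m = models$glmm$r2m, r2c = models$glmm$r2c,
                singular = models$glmm$singular),
    gamm = list(r2_adj = models$gamm$r2_adj,
                dev_expl = models$gamm$dev_expl, rho = models$gamm$rho),
    recovery = if (!is.null(recovery))
      list(rank_correlation = recovery$rank_correlation,
           sign_agreement = recovery$sign_agreement))
  jsonlite::write_json(sidecar, file.path(out_dir, "model_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  record <- list(package_version = as.character(utils::packageVersion("tonguegait")),
                 seed = cfg$seed, config = unclass(cfg),
                 input_hashes = input_hashes)
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (isTRUE(qc_plots))
    .stage(out_dir, "qc_plots",
           .qc_plots(out_dir, ptokens, palate, disp))
  invisible(list(ranges = disp$ranges, fluctuation = fluct,
                 glmm = models$glmm, comparison = models$comparison,
                 gamm = models$gamm, recovery = recovery,
                 out_dir = out_dir))
}

## QC figures: one token's slice-path traces over the palate, and the
## displacement-range vs duration scatter across cells
.qc_plots <- function(out_dir, ptokens, palate, disp) {
  pt <- ptokens[[1L]]
  local({
    grDevices::png(file.path(out_dir, "qc_token_traces.png"), width = 700,
                   height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    xr <- range(unlist(lapply(pt$positions, function(p) p[, 1L])),
                palate$x_mm)
    yr <- range(unlist(lapply(pt$positions, function(p) p[, 2L])),
                palate$y_mm)
    graphics::plot(NA, xlim = xr, ylim = yr, xlab = "x (mm)",
                   ylab = "y (mm)",
                   main = paste("Procrustean slice paths:",
                                token_key(pt$participant, pt$token_type,
                                          pt$block, pt$rate)))
    graphics::lines(palate$x_mm, palate$y_mm, col = "grey40", lwd = 2)
    cols <- seq_along(pt$positions)
    for (i in cols)
      graphics::lines(pt$positions[[i]][, 1L], pt$positions[[i]][, 2L],
                      col = i, type = "o", pch = 20, cex = 0.5)
    graphics::legend("bottomleft", legend = names(pt$positions), col = cols,
                     lty = 1, cex = 0.8)
  })
  grDevices::png(file.path(out_dir, "qc_range_duration.png"), width = 700,
                 height = 500)
  on.exit(grDevices::dev.off(), add = TRUE)
  tf <- disp$summary[disp$summary$sensor_set == "tongue_front", ]
  agg <- stats::aggregate(duration ~ participant + token_type + rate,
                          data = tf, FUN = mean)
  rg <- disp$ranges[disp$ranges$sensor_set == "tongue_front", ]
  idx <- match(paste(agg$participant, agg$token_type),
               paste(rg$participant, rg$token_type))
  agg$range <- rg$range_value[idx]
  graphics::plot(agg$range, agg$duration, col = agg$rate - 2, pch = 20,
                 xlab = "tongue-front displacement range (sd units)",
                 ylab = "token duration (s)",
                 main = "Duration vs displacement range by prompt rate")
  graphics::legend("topleft", legend = paste(sort(unique(agg$rate)), "syl/s"),
                   col = sort(unique(agg$rate)) - 2, pch = 20, cex = 0.8)
  invisible(NULL)
}
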