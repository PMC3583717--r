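pipeline_stages <- c("synth", "profiles", "foci", "coupling", "spread",
                     "tracks", "morpho")

#' Load a pipeline run configuration from a YAML file
#'
#' The file holds flat `key: value` pairs; keys must be arguments of
#' [synth_config()] or the reserved keys `stages` and `out_dir`.  Unknown
#' keys are rejected before anything runs.
#'
#' @param path YAML config path.
#' @return list with `config` (a [synth_config]), `stages`, `out_dir`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  reserved <- c("stages", "out_dir")
  unknown <- setdiff(names(raw), c(known, reserved))
  if (length(unknown))
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- do.call(synth_config, raw[intersect(names(raw), known)])
  list(config = cfg,
       stages = raw$stages %||% pipeline_stages,
       out_dir = raw$out_dir)
}

#' Run the full synthetic-embryo analysis pipeline
#'
#' Generates every synthetic input with one seeded configuration and pushes
#' it through the analysis stages in dependency order (profiles/foci feed
#' coupling conceptually; tracks feed spread and the midline; morphometrics
#' are independent), writing one CSV per result.  Every output carries a
#' header with the package version, seed and a parameter fingerprint; with
#' `reproducible = TRUE` (default) no timestamps are written, so two runs
#' with the same config are byte-identical.
#'
#' @param config a [synth_config].
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   `c("synth", "profiles", "foci", "coupling", "spread", "tracks", "morpho")`.
#' @param reproducible suppress timestamp header lines.
#' @param foci_threshold detection threshold for the foci stage, AU
#'   (default 30 percent of the configured focus intensity).
#' @return named list of per-stage result summaries, invisibly; outputs are
#'   on disk.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = pipeline_stages,
                         reproducible = TRUE,
                         foci_threshold = NULL) {
  config <- check_config(config)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  out <- function(name) file.path(out_dir, name)
  wcsv <- function(df, name)
    write_csv_with_header(df, out(name), seed = seed, params = config,
                          reproducible = reproducible)
  results <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  }

  movie <- NULL; traces <- NULL; lineage <- NULL
  blebs <- NULL; bleb_scene <- NULL; bi <- NULL
  need_movie <- any(c("synth", "profiles", "foci") %in% stages)
  if (need_movie) movie <- generate_cortex_movie(config)
  if (any(c("synth", "coupling") %in% stages))
    traces <- generate_coupled_traces(config)
  if (any(c("synth", "spread") %in% stages))
    lineage <- generate_lineage(config)
  if (any(c("synth", "morpho") %in% stages)) {
    blebs <- generate_blebs(config)
    bleb_scene <- render_bleb_outlines(blebs, config)
  }
  if (any(c("synth", "tracks") %in% stages))
    bi <- generate_bilateral_tracks(config)

  if ("synth" %in% stages) results$synth <- run_stage("synth", function() {
    write_stack(movie$stack, out("cortex_movie.tif"))
    wcsv(movie$truth, "cortex_truth.csv")
    wcsv(data.frame(time_s = traces$intensity$time_s,
                    intensity_au = traces$intensity$intensity_au,
                    tip_um = traces$extension$tip_um), "coupled_traces.csv")
    write_tracks(lineage$tracks, out("lineage_tracks.csv"), seed = seed,
                 reproducible = reproducible)
    wcsv(lineage$divisions, "divisions.csv")
    wcsv(blebs, "blebs_truth.csv")
    write_outlines(bleb_scene$outlines, out("bleb_outlines.csv"), seed = seed,
                   reproducible = reproducible)
    write_tracks(bi, out("bilateral_tracks.csv"), seed = seed,
                 reproducible = reproducible)
    list(n_foci = length(unique(movie$truth$id)), n_blebs = nrow(blebs))
  })

  if ("profiles" %in% stages)
    results$profiles <- run_stage("profiles", function() {
      ny <- config$image_shape[1L]; nx <- config$image_shape[2L]
      line <- c(2, (ny - 1) / 2, nx - 3, (ny - 1) / 2)
      prof <- line_profile(movie$stack, t = n_frames(movie$stack) %/% 2L, line)
      wcsv(as.data.frame(prof), "line_profile.csv")
      ky <- kymograph(movie$stack, line)
      kdf <- data.frame(frame = rep(ky$frames, ncol(ky$data)),
                        sample = rep(seq_len(ncol(ky$data)) - 1L,
                                     each = nrow(ky$data)),
                        intensity = as.vector(ky$data))
      wcsv(kdf, "kymograph.csv")
      list(profile_samples = nrow(prof), kymo_dim = dim(ky$data))
    })

  if ("foci" %in% stages) results$foci <- run_stage("foci", function() {
    thr <- foci_threshold %||% (0.3 * config$foci_intensity)
    det <- detect_foci_stack(movie$stack, min_intensity = thr)
    trk <- track_foci(det, max_link_dist = 3 * config$flow_speed + 2)
    wcsv(as.data.frame(trk), "focus_tracks.csv")
    ev <- count_contractions(trk, cluster_radius = 6,
                             min_gain = 2 * config$foci_intensity)
    wcsv(ev, "contractions.csv")
    list(n_detections = nrow(det), n_tracks = length(unique(trk$id)),
         n_events = nrow(ev))
  })

  if ("coupling" %in% stages)
    results$coupling <- run_stage("coupling", function() {
      nt <- normalize_traces(traces$intensity, traces$extension)
      scan <- lag_scan(nt$intensity, nt$extension)
      wcsv(as.data.frame(scan), "lag_scan.csv")
      wcsv(data.frame(peak_lag_s = scan$peak_lag, peak_r2 = scan$peak_r2),
           "coupling_summary.csv")
      list(peak_lag_s = scan$peak_lag, peak_r2 = scan$peak_r2)
    })

  if ("spread" %in% stages) results$spread <- run_stage("spread", function() {
    times <- sort(unique(c(0, config$division_times,
                           config$division_times + 1,
                           max(c(0, config$division_times)) + 600)))
    sec <- cross_sections(lineage, times)
    wcsv(sec, "cross_sections.csv")
    meas <- measured_spread(sec, tissue = "AB")
    init <- meas$spread_pct[1L]
    theo <- theoretical_spread(init, lineage$divisions, times)
    cmp <- compare_spread(meas, theo)
    wcsv(as.data.frame(meas), "spread_measured.csv")
    wcsv(as.data.frame(theo), "spread_theoretical.csv")
    wcsv(cmp$residuals, "spread_comparison.csv")
    list(rms_pct = cmp$rms_pct)
  })

  if ("tracks" %in% stages) results$tracks <- run_stage("tracks", function() {
    sm <- smooth_paths(bi)
    cm <- correlation_matrix(sm)
    cmdf <- as.data.frame(as.table(unclass(cm)))
    names(cmdf) <- c("cell_a", "cell_b", "r")
    wcsv(cmdf, "correlation_matrix.csv")
    ts <- sort(unique(bi$t))
    ang <- vapply(ts, function(tt) midline_angle(bi, tt), numeric(1))
    wcsv(data.frame(time_s = ts, midline_angle_deg = ang), "midline.csv")
    list(final_midline_deg = ang[length(ang)])
  })

  if ("morpho" %in% stages) results$morpho <- run_stage("morpho", function() {
    det <- detect_blebs(bleb_scene$outlines, bleb_scene$baseline,
                        min_area = 1, frame_interval = config$frame_interval)
    wcsv(det, "bleb_events.csv")
    if (nrow(det) >= 3L) {
      fit <- bleb_regression(det)
      wcsv(data.frame(slope = fit$slope, intercept = fit$intercept,
                      r_squared = fit$r_squared, n = fit$n),
           "bleb_regression.csv")
    }
    ## covering kinetics of a model rosette: six covering extensions advance
    ## over the target cell until it is sealed
    target <- circle_poly(c(0, 0), 10)
    cov_t <- vapply(0:10, function(k) {
      covers <- lapply(seq_len(6) - 1L, function(j) {
        ang <- j * pi / 3
        d <- 20 - 2.2 * k
        ctr <- c(d * cos(ang), d * sin(ang))
        sq <- rbind(c(-7, -7), c(7, -7), c(7, 7), c(-7, 7))
        sweep(sq, 2L, ctr, "+")
      })
      covering_fraction(target, covers)
    }, numeric(1))
    wcsv(data.frame(step = 0:10, covering_fraction = cov_t), "covering.csv")
    list(n_bleb_events = nrow(det), final_covering = cov_t[11L])
  })

  invisible(results)
}
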