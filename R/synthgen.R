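#' Configuration for the synthetic-data generators
#'
#' Holds every tunable of the generators, with defaults set to the study
#' conditions of the recordings the pipeline was built for: cortical stills
#' at 2-second intervals, extension advancement coupled to local contraction
#' intensity with a ~20 s viscoelastic delay, AB spindles deviating on
#' average by 36 degrees from the A-P axis, and bleb retraction within
#' 30-60 seconds.
#'
#' @param seed integer; fixes every generated output bit-exactly.
#' @param frame_interval seconds between frames (default 2).
#' @param pixel_size micrometres per pixel (default 0.1, high-NA confocal).
#' @param n_frames number of movie/trace frames (default 150, i.e. 300 s).
#' @param image_shape `c(Y, X)` movie size in pixels.
#' @param foci_birth_rate expected new contractile foci per frame.
#' @param foci_intensity peak focus amplitude, AU; also sets the scale of the
#'   integrated-intensity trace.
#' @param foci_sigma Gaussian focus radius, pixels.
#' @param foci_lifetime focus lifetime, frames (intensity ramps up then down).
#' @param flow_speed centripetal drift toward the apical center, px/frame.
#' @param pulse_rate contraction pulses per second in the intensity trace.
#' @param coupling_delay transport delay between local contraction intensity
#'   and extension-tip advancement, seconds (default 20).
#' @param coupling_gain extension advancement per unit of normalized
#'   intensity, micrometres (default 10).
#' @param coupling_tau half-width of the centered smoothing window applied to
#'   the intensity before coupling, seconds (default 2).
#' @param noise_sd additive measurement noise, AU (default 5; applied to the
#'   movie pixels and, suitably rescaled, to both traces).
#' @param bleb_rate bleb events per minute.
#' @param bleb_area_meanlog,bleb_area_sdlog log-normal parameters of the
#'   cross-sectional bleb area, square micrometres.
#' @param bleb_slope true anterior translocation per unit bleb area,
#'   micrometres per square micrometre (default 0.02).
#' @param bleb_noise_sd noise on the translocation, micrometres.
#' @param bleb_retraction_range retraction-duration bounds, seconds
#'   (default `c(30, 60)`).
#' @param spindle_angle_mean,spindle_angle_sd Normal parameters of the spindle
#'   angle to the A-P axis, degrees (defaults 36 and 10).
#' @param division_times times of the synchronized division rounds, seconds.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         frame_interval = 2,
                         pixel_size = 0.1,
                         n_frames = 150L,
                         image_shape = c(128L, 128L),
                         foci_birth_rate = 0.3,
                         foci_intensity = 100,
                         foci_sigma = 2,
                         foci_lifetime = 15L,
                         flow_speed = 1,
                         pulse_rate = 0.05,
                         coupling_delay = 20,
                         coupling_gain = 10,
                         coupling_tau = 2,
                         noise_sd = 5,
                         bleb_rate = 2,
                         bleb_area_meanlog = log(20),
                         bleb_area_sdlog = 0.4,
                         bleb_slope = 0.02,
                         bleb_noise_sd = 0.1,
                         bleb_retraction_range = c(30, 60),
                         spindle_angle_mean = 36,
                         spindle_angle_sd = 10,
                         division_times = c(600, 1500)) {
  cfg <- list(
    seed = check_count(seed, "seed"),
    frame_interval = check_number(frame_interval, "frame_interval", min = 1e-9),
    pixel_size = check_number(pixel_size, "pixel_size", min = 1e-9),
    n_frames = check_count(n_frames, "n_frames", min = 1L),
    image_shape = image_shape,
    foci_birth_rate = check_number(foci_birth_rate, "foci_birth_rate", min = 0),
    foci_intensity = check_number(foci_intensity, "foci_intensity", min = 0),
    foci_sigma = check_number(foci_sigma, "foci_sigma", min = 1e-9),
    foci_lifetime = check_count(foci_lifetime, "foci_lifetime", min = 2L),
    flow_speed = check_number(flow_speed, "flow_speed", min = 0),
    pulse_rate = check_number(pulse_rate, "pulse_rate", min = 0),
    coupling_delay = check_number(coupling_delay, "coupling_delay", min = 0),
    coupling_gain = check_number(coupling_gain, "coupling_gain", min = 0),
    coupling_tau = check_number(coupling_tau, "coupling_tau", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    bleb_rate = check_number(bleb_rate, "bleb_rate", min = 0),
    bleb_area_meanlog = check_number(bleb_area_meanlog, "bleb_area_meanlog"),
    bleb_area_sdlog = check_number(bleb_area_sdlog, "bleb_area_sdlog", min = 0),
    bleb_slope = check_number(bleb_slope, "bleb_slope"),
    bleb_noise_sd = check_number(bleb_noise_sd, "bleb_noise_sd", min = 0),
    bleb_retraction_range = bleb_retraction_range,
    spindle_angle_mean = check_number(spindle_angle_mean, "spindle_angle_mean",
                                      min = 0, max = 90),
    spindle_angle_sd = check_number(spindle_angle_sd, "spindle_angle_sd",
                                    min = 0),
    division_times = as.numeric(division_times)
  )
  if (length(image_shape) != 2L || any(image_shape < 1) ||
      any(image_shape != round(image_shape)))
    abort("`image_shape` must be two positive integers c(Y, X)")
  cfg$image_shape <- as.integer(image_shape)
  rr <- bleb_retraction_range
  if (length(rr) != 2L || !all(is.finite(rr)) || rr[1L] < 0 || rr[1L] > rr[2L])
    abort("`bleb_retraction_range` must be c(low, high) with 0 <= low <= high")
  if (is.unsorted(cfg$division_times))
    abort("`division_times` must be sorted ascending")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

check_config <- function(config) {
  if (!inherits(config, "synth_config"))
    abort("`config` must come from synth_config()")
  config
}

#' Generate a synthetic cortical myosin movie with ground truth
#'
#' Emulates the pulsatile cortical dynamics of internalizing cells: Gaussian
#' foci are born at the cell periphery, drift centripetally toward the apical
#' center at `flow_speed`, brighten and then dissolve (a sin^2 amplitude
#' envelope over `foci_lifetime` frames), on top of i.i.d. Gaussian pixel
#' noise.  Births avoid live foci where possible so that puncta stay
#' resolvable, as they do in the recordings before clustering.
#'
#' The seeded random stream is consumed in a documented order so that tests
#' can replay it: (1) `rpois(n_frames, foci_birth_rate)` birth counts, (2) one
#' batch of `runif` birth angles per focus (with up to 200 rejection retries
#' each), (3) pixel noise via a single `rnorm`.
#'
#' @param config a [synth_config].
#' @return a list with `stack` (an [image_stack], T x Y x X with z collapsed)
#'   and `truth`, a data frame with one row per focus and frame:
#'   `id, frame, x, y, amplitude` (0-based pixel coordinates).
#' @export
generate_cortex_movie <- function(config) {
  config <- check_config(config)
  ny <- config$image_shape[1L]; nx <- config$image_shape[2L]
  if (config$n_frames < 2L) abort("`n_frames` must be >= 2 for a movie")
  if (ny < 16L || nx < 16L) abort("`image_shape` must be at least 16 x 16")
  center <- c((nx - 1) / 2, (ny - 1) / 2)
  r_birth <- min(nx, ny) / 2 - 4 * config$foci_sigma
  with_seed(config$seed, {
    births <- stats::rpois(config$n_frames, config$foci_birth_rate)
    truth <- list(); id <- 0L
    live <- list()  # per live focus: birth frame, angle
    for (t in seq_len(config$n_frames) - 1L) {
      live <- Filter(function(f) t - f$birth < config$foci_lifetime, live)
      for (b in seq_len(births[t + 1L])) {
        id <- id + 1L
        ## rejection-sample a birth angle away from live foci
        pos <- NULL
        for (try in 1:200) {
          ang <- stats::runif(1, 0, 2 * pi)
          cand <- center + r_birth * c(cos(ang), sin(ang))
          ok <- TRUE
          for (f in live) {
            age <- t - f$birth
            fp <- center + (r_birth - age * config$flow_speed) *
              c(cos(f$angle), sin(f$angle))
            if (sum((cand - fp)^2) < (4 * config$foci_sigma)^2) { ok <- FALSE; break }
          }
          if (ok) { pos <- ang; break }
        }
        if (is.null(pos)) pos <- stats::runif(1, 0, 2 * pi)
        live[[length(live) + 1L]] <- list(id = id, birth = t, angle = pos)
        frames <- t + seq_len(config$foci_lifetime) - 1L
        frames <- frames[frames < config$n_frames]
        age <- frames - t
        r <- r_birth - age * config$flow_speed
        truth[[id]] <- data.frame(
          id = id, frame = frames,
          x = center[1L] + r * cos(pos), y = center[2L] + r * sin(pos),
          amplitude = config$foci_intensity *
            sin(pi * (age + 0.5) / config$foci_lifetime)^2)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(id = integer(), frame = integer(), x = numeric(),
                 y = numeric(), amplitude = numeric())
    ## render
    arr <- array(0, c(config$n_frames, ny, nx))
    if (nrow(truth)) {
      xs <- matrix(rep(seq_len(nx) - 1L, each = ny), ny, nx)
      ys <- matrix(rep(seq_len(ny) - 1L, nx), ny, nx)
      w <- ceiling(4 * config$foci_sigma)
      for (i in seq_len(nrow(truth))) {
        cx <- truth$x[i]; cy <- truth$y[i]
        x0 <- max(0L, floor(cx - w)); x1 <- min(nx - 1L, ceiling(cx + w))
        y0 <- max(0L, floor(cy - w)); y1 <- min(ny - 1L, ceiling(cy + w))
        if (x0 > x1 || y0 > y1) next
        gx <- exp(-((x0:x1) - cx)^2 / (2 * config$foci_sigma^2))
        gy <- exp(-((y0:y1) - cy)^2 / (2 * config$foci_sigma^2))
        arr[truth$frame[i] + 1L, (y0:y1) + 1L, (x0:x1) + 1L] <-
          arr[truth$frame[i] + 1L, (y0:y1) + 1L, (x0:x1) + 1L] +
          truth$amplitude[i] * outer(gy, gx)
      }
    }
    if (config$noise_sd > 0)
      arr <- pmax(arr + stats::rnorm(length(arr), 0, config$noise_sd), 0)
    list(stack = image_stack(arr, config$frame_interval, config$pixel_size),
         truth = truth)
  })
}

## clean (noise-free) integrated-intensity signal on the trace time grid:
## a saturating accumulation of cortical myosin plus a train of contraction
## pulses whose amplitude grows as foci become more numerous
coupled_intensity_signal <- function(config, times) {
  total <- max(times)
  ramp <- 0.6 * config$foci_intensity * (1 - exp(-times / (total / 3)))
  n_pulse <- stats::rpois(1, config$pulse_rate * total)
  onsets <- sort(stats::runif(n_pulse, 0, total))
  amps <- config$foci_intensity * stats::runif(n_pulse, 0.2, 0.6) *
    (0.5 + onsets / total)
  sig <- ramp
  for (j in seq_len(n_pulse))
    sig <- sig + amps[j] * exp(-(times - onsets[j])^2 / (2 * 3^2))
  sig
}

#' Generate a coupled intensity / extension-tip trace pair
#'
#' The integrated local contraction intensity is a saturating accumulation
#' plus a train of Gaussian contraction pulses.  The extension-tip position is
#' the smoothed, max-normalized intensity signal transported by
#' `coupling_delay` seconds and scaled by `coupling_gain`, so at zero noise
#' the delayed relationship is exact and the tip saturates toward a final
#' plateau as the intensity does.  Smoothing is a centered moving average of
#' half-width `coupling_tau`, so the configured delay is the full transport
#' delay recovered by a lag scan.  Independent Gaussian measurement noise is
#' then added to both traces (`noise_sd` AU on the intensity and the
#' equivalent relative level on the tip).
#'
#' Random stream order: pulse count, pulse onsets, pulse amplitudes,
#' intensity noise, extension noise.
#'
#' @param config a [synth_config]; requires
#'   `n_frames * frame_interval > 3 * coupling_delay`.
#' @return list with `intensity` (an [intensity_trace]), `extension` (an
#'   [extension_trace]) and `truth` (clean signal, delay, gain).
#' @export
generate_coupled_traces <- function(config) {
  config <- check_config(config)
  total <- (config$n_frames - 1L) * config$frame_interval
  if (config$n_frames * config$frame_interval <= 3 * config$coupling_delay)
    abort("trace too short: need n_frames * frame_interval > 3 * coupling_delay")
  times <- (seq_len(config$n_frames) - 1L) * config$frame_interval
  with_seed(config$seed, {
    sig <- coupled_intensity_signal(config, times)
    win <- 2L * round(config$coupling_tau / config$frame_interval) + 1L
    smoothed <- moving_average(sig, win)
    s_norm <- smoothed / max(smoothed)
    ## transport delay (linear interpolation for non-multiple delays)
    shifted <- stats::approx(times, s_norm, xout = times - config$coupling_delay,
                             rule = 2)$y
    shifted[times - config$coupling_delay < 0] <- s_norm[1L]
    tip_clean <- config$coupling_gain * shifted
    i_obs <- sig + stats::rnorm(length(sig), 0, config$noise_sd)
    tip_sd <- config$coupling_gain * config$noise_sd / max(sig)
    e_obs <- tip_clean + stats::rnorm(length(tip_clean), 0, tip_sd)
    list(intensity = intensity_trace(times, i_obs),
         extension = extension_trace(times, e_obs),
         truth = list(signal = sig, tip = tip_clean,
                      delay_s = config$coupling_delay,
                      gain = config$coupling_gain))
  })
}

fold_angle <- function(theta) {
  theta <- abs(theta) %% 180
  ifelse(theta > 90, 180 - theta, theta)
}

#' Generate a dividing surface-cell lineage on an ellipsoid
#'
#' Founder cells occupy circumferential angular intervals at the embryo
#' midpoint.  At every time in `division_times` each live cell divides: a
#' spindle angle to the A-P axis is drawn from
#' `Normal(spindle_angle_mean, spindle_angle_sd)` (folded into 0-90 degrees),
#' the cell's angular footprint grows by the coplanar-stretch factor
#' [spread_factor()] of that angle, and the two daughters split the grown
#' footprint symmetrically, with an A-P offset proportional to the cosine of
#' the spindle angle.  Lineage names follow the binary `a`/`p` suffix
#' convention.
#'
#' @param config a [synth_config].
#' @param founders data frame with columns `name`, `tissue`, `theta_start`,
#'   `theta_end` (degrees on the transverse circumference) and optionally
#'   `ap` (A-P position, micrometres).  The default is the ectodermal (AB)
#'   tissue as two equal lateral halves.
#' @param t_end end of the track time span (default past the last division).
#' @param dt_track track sampling interval, seconds.
#' @return list with `tracks` (data frame `cell, parent, tissue, t, x, y, z`),
#'   `divisions` (data frame `parent, time_s, angle_deg`), and `footprints`
#'   (data frame `cell, tissue, birth_s, death_s, theta_start, theta_end,
#'   ap`), plus the ellipsoid radii used.
#' @export
generate_lineage <- function(config,
                             founders = data.frame(
                               name = c("ABpl", "ABpr"),
                               tissue = "AB",
                               theta_start = c(15, 195),
                               theta_end = c(65, 245),
                               ap = 0),
                             t_end = NULL, dt_track = 60) {
  config <- check_config(config)
  if (nrow(founders) == 0L) abort("`founders` must contain at least one cell")
  if (is.null(founders$ap)) founders$ap <- 0
  t_end <- t_end %||% (max(c(0, config$division_times)) + 600)
  radius <- 15    # transverse radius at the embryo midpoint, um
  ap_half <- 25   # A-P semi-axis, um
  with_seed(config$seed, {
    ## each founder seeds a contiguous block of cells; the block stays tiled
    ## (adjacent, non-overlapping intervals) around its fixed angular center,
    ## growing in total width by g(theta) per dividing cell
    blocks <- lapply(seq_len(nrow(founders)), function(i) list(
      center = (founders$theta_start[i] + founders$theta_end[i]) / 2,
      cells = list(list(name = founders$name[i], parent = NA_character_,
                        tissue = founders$tissue[i], birth = 0,
                        width = founders$theta_end[i] - founders$theta_start[i],
                        ap = founders$ap[i]))))
    tile <- function(block) {
      w <- vapply(block$cells, `[[`, numeric(1), "width")
      lo <- block$center - sum(w) / 2 + cumsum(c(0, w[-length(w)]))
      for (i in seq_along(block$cells)) {
        block$cells[[i]]$lo <- lo[i]
        block$cells[[i]]$hi <- lo[i] + w[i]
      }
      block
    }
    blocks <- lapply(blocks, tile)
    divisions <- list(); done <- list()
    for (td in config$division_times) {
      for (bi in seq_along(blocks)) {
        nxt <- list()
        for (cl in blocks[[bi]]$cells) {
          theta <- fold_angle(stats::rnorm(1, config$spindle_angle_mean,
                                           config$spindle_angle_sd))
          divisions[[length(divisions) + 1L]] <-
            data.frame(parent = cl$name, time_s = td, angle_deg = theta)
          done[[length(done) + 1L]] <- c(cl, list(death = td))
          half <- cl$width * spread_factor(theta) / 2
          dap <- min(3, ap_half / 8) * cos(theta * pi / 180)
          nxt[[length(nxt) + 1L]] <- list(
            name = paste0(cl$name, "a"), parent = cl$name,
            tissue = cl$tissue, birth = td, width = half, ap = cl$ap + dap)
          nxt[[length(nxt) + 1L]] <- list(
            name = paste0(cl$name, "p"), parent = cl$name,
            tissue = cl$tissue, birth = td, width = half, ap = cl$ap - dap)
        }
        blocks[[bi]]$cells <- nxt
        blocks[[bi]] <- tile(blocks[[bi]])
      }
    }
    for (block in blocks) for (cl in block$cells)
      done[[length(done) + 1L]] <- c(cl, list(death = Inf))
    footprints <- do.call(rbind, lapply(done, function(cl) data.frame(
      cell = cl$name, parent = cl$parent, tissue = cl$tissue,
      birth_s = cl$birth, death_s = cl$death,
      theta_start = cl$lo, theta_end = cl$hi, ap = cl$ap)))
    tracks <- do.call(rbind, lapply(done, function(cl) {
      ts <- seq(cl$birth, min(cl$death, t_end), by = dt_track)
      phi <- (cl$lo + cl$hi) / 2 * pi / 180
      data.frame(cell = cl$name, parent = cl$parent, tissue = cl$tissue,
                 t = ts, x = cl$ap, y = radius * cos(phi),
                 z = radius * sin(phi))
    }))
    divisions <- do.call(rbind, divisions)
    list(tracks = tracks, divisions = divisions, footprints = footprints,
         radius = radius, ap_half = ap_half)
  })
}

#' Render cross-sections from a generated lineage
#'
#' Produces the per-timepoint angular occupancy table that
#' [measured_spread()] consumes, as seen in a transverse cross-section at the
#' embryo midpoint.
#'
#' @param lineage result of [generate_lineage()].
#' @param times timepoints (seconds) at which to render sections.
#' @param embryo embryo identifier stored in the output.
#' @return data frame `embryo, time_s, tissue, theta_start_deg, theta_end_deg`.
#' @export
cross_sections <- function(lineage, times, embryo = 1L) {
  fp <- lineage$footprints
  out <- lapply(times, function(tt) {
    live <- fp[fp$birth_s <= tt & tt < fp$death_s, , drop = FALSE]
    if (!nrow(live)) return(NULL)
    data.frame(embryo = embryo, time_s = tt, tissue = live$tissue,
               theta_start_deg = live$theta_start,
               theta_end_deg = live$theta_end)
  })
  do.call(rbind, out)
}

#' Generate a synthetic bleb event series
#'
#' Events follow a renewal process at `bleb_rate` per minute (a new onset
#' cannot begin before the previous bleb has retracted); each event has a
#' log-normal cross-sectional area, a retraction duration uniform in
#' `bleb_retraction_range`, and an anterior translocation
#' `bleb_slope * area + noise`.
#'
#' @param config a [synth_config]; the series covers
#'   `n_frames * frame_interval` seconds.
#' @return data frame `onset_s, retraction_s, area_um2, translocation_um`.
#' @export
generate_blebs <- function(config) {
  config <- check_config(config)
  total <- config$n_frames * config$frame_interval
  empty <- data.frame(onset_s = numeric(), retraction_s = numeric(),
                      area_um2 = numeric(), translocation_um = numeric())
  if (config$bleb_rate <= 0) return(empty)
  with_seed(config$seed, {
    out <- list(); t <- 0
    repeat {
      gap <- stats::rexp(1, config$bleb_rate / 60)
      onset <- t + gap
      dur <- stats::runif(1, config$bleb_retraction_range[1L],
                          config$bleb_retraction_range[2L])
      if (onset + dur > total) break
      area <- stats::rlnorm(1, config$bleb_area_meanlog, config$bleb_area_sdlog)
      transl <- config$bleb_slope * area +
        stats::rnorm(1, 0, config$bleb_noise_sd)
      out[[length(out) + 1L]] <- data.frame(
        onset_s = onset, retraction_s = onset + dur,
        area_um2 = area, translocation_um = transl)
      t <- onset + dur
    }
    if (length(out)) do.call(rbind, out) else empty
  })
}

## circle polygon helper (0-based coordinates, um)
circle_poly <- function(center, radius, n = 64L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1L] + radius * cos(a), y = center[2L] + radius * sin(a))
}

#' Render an outline time series from a bleb event table
#'
#' Builds the cell-outline polygons a segmentation would produce: a circular
#' cell body that, during each bleb, grows a rectangular anterior protrusion
#' whose area ramps linearly from zero to the event's `area_um2` and back, and
#' whose centroid translates anteriorly by `translocation_um` once the bleb
#' has retracted.  Used to exercise [detect_blebs()] against ground truth.
#'
#' @param events data frame from [generate_blebs()].
#' @param config a [synth_config] (frame interval, frame count).
#' @param cell_radius cell body radius, micrometres.
#' @return list with `outlines` (data frame `frame, time_s, x, y`) and
#'   `baseline` (the resting outline polygon at frame 0).
#' @export
render_bleb_outlines <- function(events, config, cell_radius = 5) {
  config <- check_config(config)
  times <- (seq_len(config$n_frames) - 1L) * config$frame_interval
  w <- cell_radius / 2               # protrusion width
  alpha <- asin(w / 2 / cell_radius) # half-angle subtended by the notch
  base_center <- c(0, 0)
  shift <- 0
  out <- vector("list", length(times))
  for (k in seq_along(times)) {
    tt <- times[k]
    shift <- sum(events$translocation_um[events$retraction_s <= tt])
    ev <- events[events$onset_s <= tt & tt < events$retraction_s, , drop = FALSE]
    center <- base_center + c(shift, 0)
    if (nrow(ev)) {
      ev <- ev[1L, ]
      prog <- (tt - ev$onset_s) / (ev$retraction_s - ev$onset_s)
      ## the cell body advances while the bleb retracts (second half)
      center <- center + c(ev$translocation_um * max(0, 2 * prog - 1), 0)
      ## trapezoidal area profile: the bleb holds its maximum for the middle
      ## fifth of the event, so the sampled series attains the true maximum
      frac <- min(1, 1.25 * (1 - abs(2 * prog - 1)))
      area <- ev$area_um2 * frac
      ## the rectangle replaces the circular segment beyond the notch chord,
      ## so extend it by the segment area to make the excess area exact
      seg <- cell_radius^2 * (alpha - sin(alpha) * cos(alpha))
      len <- (area + seg) / w
      a <- seq(alpha, 2 * pi - alpha, length.out = 64L)
      body <- cbind(center[1L] + cell_radius * cos(a),
                    center[2L] + cell_radius * sin(a))
      x0 <- center[1L] + cell_radius * cos(alpha)
      ## body runs +w/2 side around to -w/2 side; close through the rectangle
      poly <- rbind(body,
                    c(x0 + len, center[2L] - w / 2),
                    c(x0 + len, center[2L] + w / 2))
    } else {
      poly <- circle_poly(center, cell_radius)
    }
    out[[k]] <- data.frame(frame = k - 1L, time_s = tt,
                           x = poly[, 1L], y = poly[, 2L])
  }
  list(outlines = do.call(rbind, out),
       baseline = circle_poly(base_center, cell_radius))
}

#' Generate scripted converging focus tracks
#'
#' Builds focus tracks for a known number of contraction events: for each
#' event, `foci_per_event` tracks start on a circle around the event center
#' and converge linearly onto it while their intensities rise and fall
#' together.  Event centers sit on a jittered grid so distinct events stay
#' spatially separate; the event count is the ground truth for
#' [count_contractions()].
#'
#' @param config a [synth_config].
#' @param n_events number of scripted contraction events.
#' @param foci_per_event converging foci per event (default 3).
#' @param event_len frames per event (default 12).
#' @return data frame of tracked foci: `id, frame, x, y, intensity`.
#' @export
generate_contraction_tracks <- function(config, n_events, foci_per_event = 3L,
                                        event_len = 12L) {
  config <- check_config(config)
  n_events <- check_count(n_events, "n_events", min = 1L)
  ny <- config$image_shape[1L]; nx <- config$image_shape[2L]
  side <- ceiling(sqrt(n_events))
  gx <- (seq_len(side) - 0.5) / side * (nx - 20) + 10
  gy <- (seq_len(side) - 0.5) / side * (ny - 20) + 10
  centers <- cbind(rep(gx, side), rep(gy, each = side))[seq_len(n_events), ,
                                                        drop = FALSE]
  with_seed(config$seed, {
    centers <- centers + matrix(stats::runif(2 * n_events, -2, 2), ncol = 2L)
    out <- list(); id <- 0L
    for (ev in seq_len(n_events)) {
      t0 <- (ev - 1L) * (event_len + 3L)
      ph <- stats::runif(1, 0, 2 * pi)
      for (j in seq_len(foci_per_event)) {
        id <- id + 1L
        ang <- ph + 2 * pi * j / foci_per_event
        fr <- t0 + seq_len(event_len) - 1L
        prog <- (seq_len(event_len) - 1L) / (event_len - 1L)
        r <- 10 * (1 - prog)
        out[[id]] <- data.frame(
          id = id, frame = fr,
          x = centers[ev, 1L] + r * cos(ang),
          y = centers[ev, 2L] + r * sin(ang),
          intensity = config$foci_intensity *
            sin(pi * (prog * 0.98 + 0.01))^2)
      }
    }
    structure(do.call(rbind, out), class = c("focus_tracks", "data.frame"))
  })
}

#' Generate bilateral migration tracks
#'
#' Emulates the left/right-symmetric ectodermal lineage groups during cleft
#' closure: mirrored left/right cells converge toward the midline (so L-R
#' movement is coherent within a side and anti-correlated across sides), and
#' the right-side group, born more posteriorly, drifts anteriorly so that the
#' midline rotates onto the A-P axis.
#'
#' @param config a [synth_config] (seed, noise scale via `track_noise_sd`).
#' @param n_pairs mirrored left/right cell pairs per side.
#' @param n_steps number of timepoints.
#' @param dt_track sampling interval, seconds.
#' @param lateral0 initial distance of each side from the midline, um.
#' @param convergence fraction of `lateral0` closed by the end (0-1).
#' @param posterior_offset0 initial posterior shift of the right side, um.
#' @param coherent_sd per-step shared within-side random motion, um.
#' @param track_noise_sd per-step independent per-cell noise, um.
#' @param embryo_length A-P embryo length, um.
#' @return data frame `cell, parent, side, t, x, y, z`.
#' @export
generate_bilateral_tracks <- function(config, n_pairs = 4L, n_steps = 40L,
                                      dt_track = 60, lateral0 = 8,
                                      convergence = 0.8,
                                      posterior_offset0 = 5.5,
                                      coherent_sd = 0.25,
                                      track_noise_sd = 0.1,
                                      embryo_length = 50) {
  config <- check_config(config)
  n_pairs <- check_count(n_pairs, "n_pairs", min = 1L)
  n_steps <- check_count(n_steps, "n_steps", min = 2L)
  suffixes <- c("aa", "ap", "pa", "pp", "aaa", "aap", "apa", "app",
                "paa", "pap", "ppa", "ppp")
  if (n_pairs > length(suffixes)) abort("too many pairs requested")
  with_seed(config$seed, {
    ts <- (seq_len(n_steps) - 1L) * dt_track
    prog <- ts / max(ts)
    lateral <- lateral0 * (1 - convergence * prog)
    post <- posterior_offset0 * (1 - prog)
    wL <- cumsum(c(0, stats::rnorm(n_steps - 1L, 0, coherent_sd)))
    wR <- cumsum(c(0, stats::rnorm(n_steps - 1L, 0, coherent_sd)))
    out <- list()
    for (i in seq_len(n_pairs)) {
      x0 <- stats::runif(1, -10, 10)
      for (side in c("l", "r")) {
        nm <- paste0("ABp", side, "p", suffixes[i])
        sgn <- if (side == "l") 1 else -1
        w <- if (side == "l") wL else wR
        z <- sgn * lateral + w +
          cumsum(c(0, stats::rnorm(n_steps - 1L, 0, track_noise_sd)))
        x <- x0 + (if (side == "r") -post else 0) +
          cumsum(c(0, stats::rnorm(n_steps - 1L, 0, track_noise_sd)))
        out[[length(out) + 1L]] <- data.frame(
          cell = nm, parent = paste0("ABp", side, "p"), side = side,
          t = ts, x = x, y = 0, z = z)
      }
    }
    structure(do.call(rbind, out),
              embryo_length = embryo_length, class = "data.frame")
  })
}
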