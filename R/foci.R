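#' Detect contractile foci in a single frame
#'
#' Finds local intensity maxima above `min_intensity`, suppresses weaker
#' maxima within `min_sep` pixels of a stronger one, refines each position by
#' the intensity-weighted centroid of its 3x3 neighbourhood, and reports the
#' integrated signal in a fixed-radius disk around each focus.  Thresholds
#' are configuration, not calibrated claims: the recordings define a focus
#' only visually, as a punctate myosin accumulation.
#'
#' @param frame Y x X numeric matrix (one movie frame).
#' @param min_intensity peak-height threshold, AU.
#' @param min_sep minimum separation between detections, pixels (>= 1).
#' @param disk_radius radius of the integration disk, pixels.
#' @return data frame `x, y, intensity` (0-based pixel coordinates; `intensity`
#'   is the integrated disk signal), ordered by decreasing peak height.
#' @export
detect_foci <- function(frame, min_intensity, min_sep = 3, disk_radius = 3) {
  if (!is.matrix(frame)) abort("`frame` must be a Y x X matrix")
  check_number(min_intensity, "min_intensity")
  check_number(min_sep, "min_sep", min = 1)
  ny <- nrow(frame); nx <- ncol(frame)
  empty <- data.frame(x = numeric(), y = numeric(), intensity = numeric())
  if (ny < 3L || nx < 3L) return(empty)
  core <- frame[2:(ny - 1L), 2:(nx - 1L)]
  is_max <- core >= min_intensity
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- frame[(2:(ny - 1L)) + dy, (2:(nx - 1L)) + dx]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  py <- idx[, 1L] + 1L; px <- idx[, 2L] + 1L    # 1-based matrix indices
  peak <- frame[cbind(py, px)]
  ord <- order(peak, decreasing = TRUE)
  py <- py[ord]; px <- px[ord]; peak <- peak[ord]
  keep <- logical(length(peak))
  kx <- ky <- numeric(0)
  for (i in seq_along(peak)) {
    if (length(kx) == 0L ||
        all((px[i] - kx)^2 + (py[i] - ky)^2 >= min_sep^2)) {
      keep[i] <- TRUE
      kx <- c(kx, px[i]); ky <- c(ky, py[i])
    }
  }
  py <- py[keep]; px <- px[keep]
  ## subpixel refinement + disk-integrated intensity
  res <- t(vapply(seq_along(px), function(i) {
    ys <- max(1L, py[i] - 1L):min(ny, py[i] + 1L)
    xs <- max(1L, px[i] - 1L):min(nx, px[i] + 1L)
    w <- frame[ys, xs, drop = FALSE]
    sw <- sum(w)
    cx <- if (sw > 0) sum(rep(xs - 1L, each = length(ys)) * w) / sw else px[i] - 1L
    cy <- if (sw > 0) sum(rep(ys - 1L, length(xs)) * w) / sw else py[i] - 1L
    r <- ceiling(disk_radius)
    ys2 <- max(1L, py[i] - r):min(ny, py[i] + r)
    xs2 <- max(1L, px[i] - r):min(nx, px[i] + r)
    dsk <- outer(ys2 - 1L - cy, xs2 - 1L - cx,
                 function(a, b) a^2 + b^2 <= disk_radius^2)
    c(cx, cy, sum(frame[ys2, xs2][dsk]))
  }, numeric(3)))
  data.frame(x = res[, 1L], y = res[, 2L], intensity = res[, 3L])
}

#' Detect foci in every frame of a stack
#'
#' @param stack an [image_stack] (z max-projected per frame).
#' @inheritParams detect_foci
#' @return data frame `frame, x, y, intensity` (frame 0-based).
#' @export
detect_foci_stack <- function(stack, min_intensity, min_sep = 3,
                              disk_radius = 3) {
  out <- lapply(seq_len(n_frames(stack)) - 1L, function(t) {
    d <- detect_foci(frame_matrix(stack, t), min_intensity, min_sep,
                     disk_radius)
    if (nrow(d)) cbind(frame = t, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(frame = integer(), x = numeric(),
                               y = numeric(), intensity = numeric())
  else out
}

#' Link per-frame detections into focus tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking: candidate links between
#' active tracks and the next frame's detections are taken in order of
#' increasing distance (so the result does not depend on detection order
#' within a frame), each detection and track is used at most once, links
#' longer than `max_link_dist` are rejected, and unlinked detections start
#' new tracks.  Global assignment is deliberately not used: focus densities
#' in these recordings are low and greedy linking is transparent.
#'
#' @param detections data frame `frame, x, y, intensity` as from
#'   [detect_foci_stack()].
#' @param max_link_dist maximum frame-to-frame displacement, pixels.
#' @return data frame of class `focus_tracks`: `id, frame, x, y, intensity`,
#'   with track ids ordered by birth frame.
#' @export
track_foci <- function(detections, max_link_dist) {
  check_number(max_link_dist, "max_link_dist", min = 1e-12)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(detections)))
    abort("`detections` needs columns frame, x, y")
  if (is.null(detections$intensity)) detections$intensity <- NA_real_
  empty <- structure(data.frame(id = integer(), frame = integer(),
                                x = numeric(), y = numeric(),
                                intensity = numeric()),
                     class = c("focus_tracks", "data.frame"))
  if (nrow(detections) == 0L) return(empty)
  frames <- sort(unique(detections$frame))
  rows <- vector("list", length(frames))
  active <- data.frame(id = integer(), x = numeric(), y = numeric())
  next_id <- 1L
  for (k in seq_along(frames)) {
    det <- detections[detections$frame == frames[k], , drop = FALSE]
    link_id <- rep(NA_integer_, nrow(det))
    if (nrow(active) && k > 1L && frames[k] == frames[k - 1L] + 1L) {
      dmat <- outer(active$x, det$x, "-")^2 + outer(active$y, det$y, "-")^2
      cand <- which(dmat <= max_link_dist^2, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        used_tr <- logical(nrow(active)); used_de <- logical(nrow(det))
        for (i in seq_len(nrow(cand))) {
          tr <- cand[i, 1L]; de <- cand[i, 2L]
          if (!used_tr[tr] && !used_de[de]) {
            link_id[de] <- active$id[tr]
            used_tr[tr] <- TRUE; used_de[de] <- TRUE
          }
        }
      }
    }
    fresh <- is.na(link_id)
    if (any(fresh)) {
      link_id[fresh] <- next_id + seq_len(sum(fresh)) - 1L
      next_id <- next_id + sum(fresh)
    }
    rows[[k]] <- data.frame(id = link_id, frame = det$frame,
                            x = det$x, y = det$y, intensity = det$intensity)
    active <- data.frame(id = link_id, x = det$x, y = det$y)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$frame), ]
  rownames(out) <- NULL
  structure(out, class = c("focus_tracks", "data.frame"))
}

#' Count contraction events from focus tracks
#'
#' Groups tracks whose paths converge (single-linkage clustering of track end
#' positions cut at `cluster_radius`) and scans each group's summed intensity
#' over time for pulses: an event is emitted when the summed intensity rises
#' by at least `min_gain` above its running minimum and subsequently falls by
#' at least `min_gain / 2` from the peak.  Convergence-based grouping mirrors
#' the visual definition of a contraction as streams of foci converging onto
#' one spot.
#'
#' @param tracks a `focus_tracks` data frame from [track_foci()].
#' @param cluster_radius spatial radius for grouping converging tracks, px.
#' @param min_gain minimum summed-intensity rise for an event, AU.
#' @return data frame `event, onset_frame, peak_frame, centroid_x, centroid_y,
#'   n_foci, focus_ids, gain`, ordered by onset.
#' @export
count_contractions <- function(tracks, cluster_radius, min_gain) {
  check_number(cluster_radius, "cluster_radius", min = 1e-12)
  check_number(min_gain, "min_gain", min = 0)
  empty <- data.frame(event = integer(), onset_frame = integer(),
                      peak_frame = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), n_foci = integer(),
                      focus_ids = character(), gain = numeric())
  if (is.null(tracks) || nrow(tracks) == 0L) return(empty)
  ends <- do.call(rbind, lapply(split(tracks, tracks$id), function(tr) {
    tr[which.max(tr$frame), c("id", "x", "y")]
  }))
  cl <- if (nrow(ends) == 1L) 1L else
    stats::cutree(stats::hclust(stats::dist(ends[, c("x", "y")]),
                                method = "single"), h = cluster_radius)
  events <- list()
  for (g in unique(cl)) {
    ids <- ends$id[cl == g]
    sub <- tracks[tracks$id %in% ids, , drop = FALSE]
    ssum <- tapply(sub$intensity, sub$frame, sum)
    fr <- as.integer(names(ssum)); v <- as.numeric(ssum)
    ord <- order(fr); fr <- fr[ord]; v <- v[ord]
    ## hysteresis pulse scan
    run_min <- v[1L]; run_min_i <- 1L; state <- "low"
    peak <- -Inf; peak_i <- NA_integer_; onset_i <- NA_integer_
    for (i in seq_along(v)) {
      if (state == "low") {
        if (v[i] < run_min) { run_min <- v[i]; run_min_i <- i }
        if (v[i] - run_min >= min_gain && min_gain > 0) {
          state <- "high"; onset_i <- run_min_i; peak <- v[i]; peak_i <- i
        }
      } else {
        if (v[i] > peak) { peak <- v[i]; peak_i <- i }
        if (peak - v[i] >= min_gain / 2) {
          events[[length(events) + 1L]] <- data.frame(
            onset_frame = fr[onset_i], peak_frame = fr[peak_i],
            centroid_x = mean(ends$x[cl == g]),
            centroid_y = mean(ends$y[cl == g]),
            n_foci = length(ids),
            focus_ids = paste(sort(ids), collapse = ";"),
            gain = peak - v[onset_i])
          state <- "low"; run_min <- v[i]; run_min_i <- i
        }
      }
    }
  }
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  out <- out[order(out$onset_frame), ]
  cbind(event = seq_len(nrow(out)), out, row.names = NULL)
}

#' Detect bleb events from an outline time series
#'
#' A bleb is a transient protrusion: the area of the outline outside the
#' (aligned) resting baseline outline exceeds `min_area` for a run of frames
#' and then regresses.  For each event the maximum excess area, onset and
#' retraction times, and the anterior displacement of the outline centroid
#' from just before onset to just after retraction are reported.
#'
#' Because the blebbing cell translocates between events, the baseline shape
#' is aligned to each frame before the set difference is taken:
#' `align = "anterior"` (default) translates the baseline so its posterior
#' extreme (minimum x, anterior being +x) and centroid height match the
#' frame's outline; `align = "none"` compares in fixed coordinates.
#'
#' @param outlines data frame `frame, x, y` (micrometres), one closed polygon
#'   per frame; an optional `time_s` column supplies times, otherwise
#'   `frame * frame_interval` is used.
#' @param baseline resting outline polygon (matrix or data frame with x, y).
#' @param min_area excess-area threshold, square micrometres.
#' @param frame_interval seconds per frame (used when `time_s` is absent).
#' @param align baseline alignment mode, see Details.
#' @return data frame `event, onset_s, retraction_s, max_area_um2,
#'   translocation_um`.
#' @export
detect_blebs <- function(outlines, baseline, min_area,
                         frame_interval = 2, align = c("anterior", "none")) {
  align <- match.arg(align)
  check_number(min_area, "min_area", min = 0)
  if (!all(c("frame", "x", "y") %in% names(outlines)))
    abort("`outlines` needs columns frame, x, y")
  base <- as_poly(baseline, "baseline")
  if (!poly_is_simple(base)) abort("`baseline` polygon is self-intersecting")
  frames <- sort(unique(outlines$frame))
  times <- if (!is.null(outlines$time_s))
    vapply(frames, function(f)
      outlines$time_s[outlines$frame == f][1L], numeric(1))
  else frames * frame_interval
  excess <- numeric(length(frames))
  cent_x <- numeric(length(frames))
  for (k in seq_along(frames)) {
    p <- as_poly(outlines[outlines$frame == frames[k], c("x", "y")],
                 "outline")
    b <- base
    if (align == "anterior") {
      dx <- min(p[, 1L]) - min(b[, 1L])
      dy <- polygon_centroid(p)[2L] - polygon_centroid(b)[2L]
      b <- cbind(b[, 1L] + dx, b[, 2L] + dy)
    }
    excess[k] <- polygon_area(p) - area_in_target(p, list(b))
    cent_x[k] <- polygon_centroid(p)[1L]
  }
  above <- excess >= min_area & excess > 0
  if (!any(above))
    return(data.frame(event = integer(), onset_s = numeric(),
                      retraction_s = numeric(), max_area_um2 = numeric(),
                      translocation_um = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- lapply(seq_along(runs), function(j) {
    s <- starts[runs[j]]; e <- ends[runs[j]]
    pre <- max(1L, s - 1L); post <- min(length(frames), e + 1L)
    data.frame(onset_s = times[s], retraction_s = times[e],
               max_area_um2 = max(excess[s:e]),
               translocation_um = cent_x[post] - cent_x[pre])
  })
  out <- do.call(rbind, out)
  cbind(event = seq_len(nrow(out)), out)
}
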