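## Migration-path analysis from lineage track tables.
##
## A track table is a long data frame with columns `cell, t, x, y, z`
## (seconds and micrometres in embryo axes: x = A-P with anterior positive,
## y = D-V, z = L-R) and optionally `parent`.  Functions that take a single
## track accept the rows of one cell.

check_track <- function(track, name = "track") {
  need <- c("t", "x", "y", "z")
  if (!all(need %in% names(track)))
    abort(sprintf("`%s` needs columns t, x, y, z", name))
  if (nrow(track) && is.unsorted(track$t, strictly = TRUE))
    abort(sprintf("`%s` timepoints must be strictly increasing", name))
  if (!all(is.finite(as.matrix(track[, need]))))
    abort(sprintf("`%s` has non-finite values", name))
  track
}

#' Smooth a migration path
#'
#' Centered moving average per coordinate (default width five timepoints,
#' the convention for these lineage tracks); windows shrink symmetrically at
#' the ends of the track, and timestamps are unchanged.
#'
#' @param track data frame for one cell, columns `t, x, y, z`.
#' @param window odd window width (default 5).
#' @return the track with smoothed coordinates.
#' @export
smooth_path <- function(track, window = 5) {
  track <- check_track(track)
  for (cc in c("x", "y", "z"))
    track[[cc]] <- moving_average(track[[cc]], window)
  track
}

#' Smooth every track in a table
#'
#' @param tracks long track table with a `cell` column.
#' @inheritParams smooth_path
#' @return the table with smoothed coordinates.
#' @export
smooth_paths <- function(tracks, window = 5) {
  parts <- lapply(split(tracks, tracks$cell), smooth_path, window = window)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Left/right movement correlation of two cells
#'
#' Pearson correlation of the two cells' movement along the L-R axis (z)
#' over the timepoints at which both are present.  By default per-step
#' displacement increments are correlated rather than raw positions, since
#' position correlation is dominated by shared drift; raw-position mode is
#' available behind `on = "positions"`.
#'
#' @param a,b single-cell track data frames.
#' @param on correlate `"increments"` (default) or `"positions"`.
#' @param min_overlap minimum shared timepoints (default 3); pairs below it
#'   return `NA` and are excluded from matrices.
#' @return correlation coefficient in \[-1, 1\], or `NA` if the overlap is too
#'   short or a series is constant.
#' @export
lr_correlation <- function(a, b, on = c("increments", "positions"),
                           min_overlap = 3) {
  on <- match.arg(on)
  a <- check_track(a, "a"); b <- check_track(b, "b")
  shared <- intersect(a$t, b$t)
  if (length(shared) < min_overlap) return(NA_real_)
  za <- a$z[match(shared, a$t)]
  zb <- b$z[match(shared, b$t)]
  if (on == "increments") { za <- diff(za); zb <- diff(zb) }
  if (stats::sd(za) == 0 || stats::sd(zb) == 0) return(NA_real_)
  stats::cor(za, zb)
}

#' Pairwise movement-correlation matrix
#'
#' All pairwise [lr_correlation()] values for a track table, as displayed in
#' movement heat maps: symmetric, unit diagonal, entries in \[-1, 1\].  The
#' clip range (default 0.8) applies only to the rendered heat map, never to
#' the stored values.  Sister-cell paths can optionally be combined into a
#' single path (positions averaged over shared times, named after the
#' parent) before correlation.
#'
#' @param tracks long track table with `cell` column.
#' @param clip display clip for [plot.correlation_matrix()] (default 0.8).
#' @param combine_sisters average sister paths (cells sharing a parent name
#'   prefix, i.e. names equal up to the final a/p/l/r letter) before
#'   correlating.
#' @inheritParams lr_correlation
#' @return matrix of class `correlation_matrix` with a `clip` attribute.
#' @export
correlation_matrix <- function(tracks, clip = 0.8, combine_sisters = FALSE,
                               on = c("increments", "positions")) {
  on <- match.arg(on)
  if (!"cell" %in% names(tracks)) abort("`tracks` needs a `cell` column")
  if (length(unique(tracks$cell)) < 2L) abort("need at least two tracks")
  if (combine_sisters) tracks <- combine_sister_paths(tracks)
  cells <- unique(tracks$cell)
  per <- split(tracks, tracks$cell)[cells]
  n <- length(cells)
  m <- diag(1, n)
  dimnames(m) <- list(cells, cells)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    m[i, j] <- m[j, i] <- lr_correlation(per[[i]], per[[j]], on = on)
  structure(m, clip = clip, class = c("correlation_matrix", "matrix"))
}

combine_sister_paths <- function(tracks) {
  stem <- sub("[aplr]$", "", tracks$cell)
  parts <- lapply(split(tracks, stem), function(g) {
    agg <- stats::aggregate(g[, c("x", "y", "z")], by = list(t = g$t), mean)
    cnt <- table(g$t)
    agg <- agg[cnt[as.character(agg$t)] == length(unique(g$cell)), ,
               drop = FALSE]
    cbind(cell = stem[match(g$cell[1L], tracks$cell)], agg)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' @export
plot.correlation_matrix <- function(x, ...) {
  clip <- attr(x, "clip") %||% 0.8
  z <- pmin(pmax(unclass(x), -clip), clip)
  n <- nrow(z)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(seq_len(n), seq_len(n), t(z[n:1, , drop = FALSE]),
                  zlim = c(-clip, clip), col = pal, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(n), colnames(z), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(z)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Net displacement as percent of embryo length
#'
#' Signed projection of a cell's net displacement between two times onto an
#' axis, as a percentage of the embryo length (the scale used to report,
#' e.g., an ~11 percent anterior movement during rosette engagement).
#'
#' @param track single-cell track data frame.
#' @param axis 3D direction (default anterior, `c(1, 0, 0)`).
#' @param embryo_length embryo length, micrometres; defaults to the A-P
#'   extent of the track's own bounding box only if supplied as `NULL` is
#'   not allowed - pass the measured length.
#' @param t0,t1 start and end times, seconds (default track span).
#' @return displacement, percent of embryo length (signed).
#' @export
displacement_metrics <- function(track, axis = c(1, 0, 0), embryo_length,
                                 t0 = NULL, t1 = NULL) {
  track <- check_track(track)
  check_number(embryo_length, "embryo_length", min = 1e-12)
  axis <- as.numeric(axis)
  if (length(axis) != 3L || sqrt(sum(axis^2)) < .Machine$double.eps)
    abort("`axis` must be a non-zero 3D vector")
  axis <- axis / sqrt(sum(axis^2))
  t0 <- t0 %||% min(track$t); t1 <- t1 %||% max(track$t)
  if (!(t0 < t1)) abort("`t0` must be earlier than `t1`")
  if (t0 < min(track$t) || t1 > max(track$t))
    abort("`t0`/`t1` outside the track's time span")
  p <- function(tt) {
    i <- which.min(abs(track$t - tt))
    c(track$x[i], track$y[i], track$z[i])
  }
  sum((p(t1) - p(t0)) * axis) / embryo_length * 100
}

#' Mirror a lineage name across the midline
#'
#' Swaps the `l` and `r` letters of the binary lineage nomenclature
#' (e.g. `ABplp` to `ABprp`); founder prefixes in capitals are untouched.
#'
#' @param name character vector of lineage names.
#' @return mirrored names.
#' @export
mirror_name <- function(name) chartr("lr", "rl", name)

#' Midline angle to the A-P axis
#'
#' Matched left/right cell pairs are identified by lineage-name mirroring
#' ([mirror_name()]).  For each pair present at time `t` the left-minus-right
#' difference vector is taken in the surface plane (x = A-P, z = L-R); the
#' midline is perpendicular to the mean difference vector, and its angle to
#' the A-P axis is returned in degrees.
#'
#' Sign convention: positive when the right-side group sits posterior to its
#' left partners (i.e. the anterior end of the midline is deflected toward
#' the right side); 0 for perfect mirror symmetry.  A decreasing angle over
#' time indicates symmetrization of the surface layer.
#'
#' @param tracks long track table with `cell` column.
#' @param t time (seconds) at which to evaluate; the nearest timepoint of
#'   each track is used.
#' @param pairs optional two-column character matrix of (left, right) names;
#'   by default pairs are auto-matched by name mirroring, and an error lists
#'   any cell with no partner.
#' @return angle in degrees.
#' @export
midline_angle <- function(tracks, t, pairs = NULL) {
  if (!"cell" %in% names(tracks)) abort("`tracks` needs a `cell` column")
  cells <- unique(tracks$cell)
  if (is.null(pairs)) {
    lefts <- cells[grepl("l", sub("^[A-Z0-9]+", "", cells))]
    partner <- mirror_name(lefts)
    missing <- lefts[!partner %in% cells]
    if (length(missing))
      abort(paste("no right-side partner for:", paste(missing, collapse = ", ")))
    pairs <- cbind(lefts, partner[partner %in% cells])
  }
  if (nrow(pairs) < 2L) abort("need at least two left/right pairs")
  pos <- function(cell) {
    tr <- tracks[tracks$cell == cell, , drop = FALSE]
    i <- which.min(abs(tr$t - t))
    c(tr$x[i], tr$z[i])
  }
  d <- t(apply(pairs, 1L, function(pr) pos(pr[1L]) - pos(pr[2L])))
  md <- colMeans(d)  # (dx, dz), left minus right
  if (sqrt(sum(md^2)) < .Machine$double.eps)
    abort("left and right groups coincide; midline undefined")
  atan2(md[1L], md[2L]) * 180 / pi
}
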