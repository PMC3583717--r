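#' Write an image stack as multi-page TIFF with a metadata sidecar
#'
#' Pages are written frame-major (all z of frame 0, then frame 1, ...).
#' Integer-valued stacks up to 65535 are stored as 16-bit samples and
#' round-trip exactly; other data are stored as 32-bit samples scaled into
#' \[0, 1\] by a power-of-two factor (quantization error below 2^-31
#' relative).  The acquisition metadata and the scale go into a YAML sidecar
#' (`<path>.yml`).
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack")
  d <- dim(stack$data)
  mx <- max(stack$data)
  uint16 <- mx <= 65535 && all(stack$data == round(stack$data))
  scale <- if (uint16) 65535 else if (mx <= 0) 1 else 2^ceiling(log2(mx))
  bits <- if (uint16) 16L else 32L
  pages <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (t in seq_len(d[1L])) for (z in seq_len(d[2L])) {
    k <- k + 1L
    pages[[k]] <- matrix(stack$data[t, z, , ] / scale, d[3L], d[4L])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  yaml::write_yaml(list(frame_interval = stack$frame_interval,
                        pixel_size = stack$pixel_size,
                        z_spacing = stack$z_spacing,
                        n_z = d[2L], intensity_scale = scale,
                        sample_type = if (uint16) "uint16" else "scaled"),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Metadata (frame interval, pixel size) come from the YAML sidecar written
#' by [write_stack()] or from the explicit arguments, which take precedence;
#' missing metadata is an error, never a silent default.
#'
#' @param path TIFF path.
#' @param frame_interval,pixel_size,z_spacing acquisition metadata overriding
#'   the sidecar.
#' @param n_z z-planes per frame (sidecar value, or 1).
#' @return an [image_stack].
#' @export
read_stack <- function(path, frame_interval = NULL, pixel_size = NULL,
                       z_spacing = NULL, n_z = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  meta <- list()
  sidecar <- paste0(path, ".yml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
                      abort(sprintf("cannot parse TIFF '%s': %s",
                                    path, conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) abort(sprintf("'%s' contains no pages", path))
  frame_interval <- frame_interval %||% meta$frame_interval
  pixel_size <- pixel_size %||% meta$pixel_size
  z_spacing <- z_spacing %||% meta$z_spacing %||% 1
  n_z <- n_z %||% meta$n_z %||% 1L
  if (is.null(frame_interval) || is.null(pixel_size))
    abort("frame_interval and pixel_size must come from the sidecar or arguments")
  scale <- meta$intensity_scale %||% 1
  uint16 <- identical(meta$sample_type, "uint16")
  if (length(pages) %% n_z != 0L)
    abort(sprintf("page count %d is not a multiple of n_z = %d (truncated file?)",
                  length(pages), n_z))
  nt <- length(pages) %/% n_z
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, c(nt, n_z, ny, nx))
  k <- 0L
  for (t in seq_len(nt)) for (z in seq_len(n_z)) {
    k <- k + 1L
    pg <- pages[[k]]
    if (nrow(pg) != ny || ncol(pg) != nx)
      abort(sprintf("page %d has inconsistent dimensions", k))
    arr[t, z, , ] <- if (uint16) round(pg * scale) else pg * scale
  }
  image_stack(arr, frame_interval, pixel_size, z_spacing)
}

lineage_grammar <- "^(AB|MS|EMS|E|C|D|P[0-9]|Z[23])[aplrdv]*$"

#' Read a cell-track table
#'
#' Two dialects are supported.  `"csv"` is the canonical format: columns
#' `cell, t_s, x_um, y_um, z_um` and optionally `parent` with a mandatory
#' header (comment lines starting with `#` are ignored).
#' `"acetree-nuclei"` is a simplified read-only nuclei listing with columns
#' `time, index, status, predecessor, x, y, z, diameter, name`; records with
#' `status <= 0` are dropped and tracks are grouped by `name`.
#'
#' Lineage names are checked against the binary nomenclature grammar,
#' duplicate (cell, time) records and non-monotone times are errors naming
#' the offending row.
#'
#' @param path input file.
#' @param dialect `"csv"` or `"acetree-nuclei"`.
#' @return track table: `cell, t, x, y, z, parent`.
#' @export
read_tracks <- function(path, dialect = c("csv", "acetree-nuclei")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  raw <- read_csv_skip_comments(path)
  if (dialect == "csv") {
    need <- c("cell", "t_s", "x_um", "y_um", "z_um")
    if (!all(need %in% names(raw)))
      abort(paste("track CSV needs columns", paste(need, collapse = ", ")))
    df <- data.frame(cell = as.character(raw$cell), t = raw$t_s,
                     x = raw$x_um, y = raw$y_um, z = raw$z_um,
                     parent = if (is.null(raw$parent)) NA_character_
                              else as.character(raw$parent))
  } else {
    need <- c("time", "index", "status", "predecessor", "x", "y", "z",
              "diameter", "name")
    if (!all(need %in% names(raw)))
      abort(paste("acetree-nuclei listing needs columns",
                  paste(need, collapse = ", ")))
    raw <- raw[raw$status > 0, , drop = FALSE]
    df <- data.frame(cell = as.character(raw$name), t = raw$time,
                     x = raw$x, y = raw$y, z = raw$z, parent = NA_character_)
  }
  bad <- which(!grepl(lineage_grammar, df$cell))
  if (length(bad))
    abort(sprintf("invalid lineage name '%s' at row %d",
                  df$cell[bad[1L]], bad[1L]))
  key <- paste(df$cell, df$t)
  if (anyDuplicated(key))
    abort(sprintf("duplicate (cell, time) record at row %d",
                  which(duplicated(key))[1L]))
  for (cl in unique(df$cell)) {
    idx <- which(df$cell == cl)
    if (is.unsorted(df$t[idx], strictly = TRUE))
      abort(sprintf("non-monotone time for cell '%s' at row %d", cl,
                    idx[which(diff(df$t[idx]) <= 0)[1L] + 1L]))
  }
  if (!all(is.finite(as.matrix(df[, c("t", "x", "y", "z")]))))
    abort("track table has non-finite coordinates")
  df
}

#' Write a cell-track table in the canonical CSV dialect
#'
#' @param tracks track table (`cell, t, x, y, z[, parent]`).
#' @param path output path.
#' @param seed seed recorded in the header.
#' @param reproducible suppress the timestamp header line.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, seed = NA, reproducible = TRUE) {
  df <- data.frame(cell = tracks$cell, t_s = tracks$t, x_um = tracks$x,
                   y_um = tracks$y, z_um = tracks$z,
                   parent = tracks$parent %||% NA_character_)
  write_csv_with_header(df, path, seed = seed, params = names(df),
                        reproducible = reproducible)
}

#' Read / write outline polygons
#'
#' Outline CSVs carry one vertex per row: `frame, vertex_index, x, y` plus
#' optional `label` and `time_s` columns; coordinates are micrometres unless
#' the caller's convention says otherwise.
#'
#' @param path file path.
#' @return data frame `frame, vertex_index, x, y[, label, time_s]`.
#' @export
read_outlines <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- read_csv_skip_comments(path)
  need <- c("frame", "vertex_index", "x", "y")
  if (!all(need %in% names(df)))
    abort(paste("outline CSV needs columns", paste(need, collapse = ", ")))
  df[order(df$frame, df$vertex_index), , drop = FALSE]
}

#' @rdname read_outlines
#' @param outlines data frame `frame, x, y[, label, time_s]`; vertex order
#'   within a frame is preserved.
#' @inheritParams write_tracks
#' @export
write_outlines <- function(outlines, path, seed = NA, reproducible = TRUE) {
  idx <- stats::ave(seq_len(nrow(outlines)), outlines$frame,
                    FUN = seq_along) - 1L
  df <- cbind(frame = outlines$frame, vertex_index = idx,
              outlines[, setdiff(names(outlines), c("frame")), drop = FALSE])
  write_csv_with_header(df, path, seed = seed, params = names(df),
                        reproducible = reproducible)
}
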