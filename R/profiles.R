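## Line-profile and kymograph measurement.
##
## Coordinates are 0-based and pixel-centered: the sample at (x, y) = (0, 0)
## is the center of the top-left pixel.  Sampling uses bilinear interpolation
## with coordinates clamped to the image border.

bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 0), nx - 1); y <- pmin(pmax(y, 0), ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  if (nx == 1L) x0 <- x * 0
  if (ny == 1L) y0 <- y * 0
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1L, x0 + 1L)]
  i01 <- img[cbind(y0 + 1L, pmin(x0 + 2L, nx))]
  i10 <- img[cbind(pmin(y0 + 2L, ny), x0 + 1L)]
  i11 <- img[cbind(pmin(y0 + 2L, ny), pmin(x0 + 2L, nx))]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

check_line <- function(stack, line) {
  if (!is.numeric(line) || length(line) != 4L)
    abort("`line` must be numeric c(x0, y0, x1, y1) in pixels")
  d <- dim(stack$data)
  nx <- d[4L]; ny <- d[3L]
  p <- matrix(line, 2L, 2L, byrow = TRUE)
  for (i in 1:2) {
    if (p[i, 1L] < 0 || p[i, 1L] > nx - 1 || p[i, 2L] < 0 || p[i, 2L] > ny - 1)
      abort(sprintf("line endpoint %d at (%g, %g) is outside the %dx%d image",
                    i, p[i, 1L], p[i, 2L], nx, ny))
  }
  p
}

## positions of samples along a line at exactly 1 px spacing
line_samples <- function(p0, p1) {
  len <- sqrt(sum((p1 - p0)^2))
  if (len < .Machine$double.eps) abort("line has zero length")
  s <- seq(0, floor(len))
  u <- (p1 - p0) / len
  list(s = s, x = p0[1L] + s * u[1L], y = p0[2L] + s * u[2L], u = u, len = len)
}

#' Fluorescence line profile with parallel-line averaging
#'
#' Samples the image along the requested line and along `n_lines - 1`
#' additional parallel lines offset perpendicular to it, then reports the
#' per-position mean and sample standard deviation across lines.  This is the
#' measurement convention for intensity histograms along a membrane: two
#' parallel lines spaced at one pixel, shown as mean and SD.
#'
#' With an even `n_lines` the offsets start on the requested line and step to
#' one side (`0, spacing, ...`); with an odd `n_lines` they are symmetric
#' about it.  Sampling is bilinear at exactly 1 px steps along the line.
#'
#' @param stack an [image_stack]; z is max-projected if present.
#' @param t frame index (0-based).
#' @param line numeric `c(x0, y0, x1, y1)` in pixels; both endpoints must be
#'   inside the image.
#' @param n_lines number of parallel lines (default 2).
#' @param spacing_px perpendicular spacing between lines in pixels (default 1).
#' @return a data frame of class `line_profile` with columns `position_um`,
#'   `mean`, `sd`, and attributes `n_lines`, `pixel_size`.
#' @export
line_profile <- function(stack, t, line, n_lines = 2, spacing_px = 1) {
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack")
  n_lines <- check_count(n_lines, "n_lines", min = 1L)
  check_number(spacing_px, "spacing_px", min = 0)
  p <- check_line(stack, line)
  img <- frame_matrix(stack, t)
  ls <- line_samples(p[1L, ], p[2L, ])
  nrm <- c(-ls$u[2L], ls$u[1L])  # unit normal
  offsets <- if (n_lines %% 2L == 0L) spacing_px * (seq_len(n_lines) - 1L)
             else spacing_px * (seq_len(n_lines) - 1L - (n_lines - 1L) %/% 2L)
  vals <- vapply(offsets, function(o)
    bilinear_sample(img, ls$x + o * nrm[1L], ls$y + o * nrm[2L]),
    numeric(length(ls$s)))
  vals <- matrix(vals, nrow = length(ls$s))
  out <- data.frame(
    position_um = ls$s * stack$pixel_size,
    mean = rowMeans(vals),
    sd = if (n_lines == 1L) rep(0, length(ls$s)) else apply(vals, 1L, stats::sd)
  )
  attr(out, "n_lines") <- n_lines
  attr(out, "pixel_size") <- stack$pixel_size
  class(out) <- c("line_profile", "data.frame")
  out
}

#' Kymograph along a line
#'
#' Builds the space-time image of single-line profiles over a frame range:
#' row `t` is the bilinear profile of frame `t` along the line at 1 px
#' sampling.  Shares its sampler with [line_profile()], so a kymograph row
#' equals the `n_lines = 1` profile at the same frame.
#'
#' @inheritParams line_profile
#' @param frames 0-based frame indices (default all frames).
#' @return an object of class `kymograph`: list with `data` (T x S matrix),
#'   `line`, `frames`, `frame_interval`, `pixel_size`.
#' @export
kymograph <- function(stack, line, frames = NULL) {
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack")
  frames <- frames %||% (seq_len(n_frames(stack)) - 1L)
  if (length(frames) == 0L) abort("empty frame range")
  p <- check_line(stack, line)
  ls <- line_samples(p[1L, ], p[2L, ])
  rows <- vapply(frames, function(t)
    bilinear_sample(frame_matrix(stack, t), ls$x, ls$y),
    numeric(length(ls$s)))
  structure(list(data = t(matrix(rows, nrow = length(ls$s))),
                 line = as.numeric(line), frames = as.integer(frames),
                 frame_interval = stack$frame_interval,
                 pixel_size = stack$pixel_size),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d samples along (%g,%g)-(%g,%g)\n",
              nrow(x$data), ncol(x$data),
              x$line[1L], x$line[2L], x$line[3L], x$line[4L]))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = x$frames * x$frame_interval,
                  y = seq_len(ncol(x$data)) * x$pixel_size,
                  z = x$data, xlab = "time (s)", ylab = "position (um)",
                  useRaster = TRUE, ...)
  invisible(x)
}
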