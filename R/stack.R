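#' Construct an image stack
#'
#' Container for a single-channel T x Z x Y x X intensity array with the
#' acquisition metadata used throughout the pipeline.  A 3-dimensional array
#' is interpreted as T x Y x X (a single z-plane, e.g. a cortical projection).
#'
#' @param data numeric array, T x Z x Y x X or T x Y x X; intensities must be
#'   finite and non-negative.
#' @param frame_interval time between frames, seconds.
#' @param pixel_size lateral pixel size, micrometres per pixel.
#' @param z_spacing spacing between z-sections, micrometres.
#' @return an object of class `image_stack` with elements `data` (always
#'   4-dimensional), `frame_interval`, `pixel_size`, `z_spacing`.
#' @export
image_stack <- function(data, frame_interval, pixel_size, z_spacing = 1) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    abort("`data` must be a 3- or 4-dimensional array (T[,Z],Y,X)")
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data)[1L], 1L, dim(data)[2L], dim(data)[3L])
  if (any(dim(data) < 1L)) abort("all stack dimensions must be >= 1")
  if (!all(is.finite(data)) || any(data < 0))
    abort("stack intensities must be finite and >= 0")
  check_number(frame_interval, "frame_interval", min = 1e-12)
  check_number(pixel_size, "pixel_size", min = 1e-12)
  check_number(z_spacing, "z_spacing", min = 1e-12)
  structure(list(data = data, frame_interval = frame_interval,
                 pixel_size = pixel_size, z_spacing = z_spacing),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_stack: %d frame(s) x %d z x %d y x %d x, dt=%gs, px=%g um, dz=%g um\n",
    d[1L], d[2L], d[3L], d[4L], x$frame_interval, x$pixel_size, x$z_spacing))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1L]

## Y x X matrix for one frame (max-projected over z if needed)
frame_matrix <- function(stack, t, z = NULL) {
  d <- dim(stack$data)
  t <- check_count(t, "t", min = 0L)
  if (t >= d[1L]) abort(sprintf("frame %d out of range (stack has %d frames)",
                                t, d[1L]))
  if (!is.null(z)) return(stack$data[t + 1L, z + 1L, , ])
  m <- stack$data[t + 1L, 1L, , ]
  if (d[2L] > 1L) for (z in 2:d[2L]) m <- pmax(m, stack$data[t + 1L, z, , ])
  matrix(m, nrow = d[3L], ncol = d[4L])
}

#' Maximum-intensity projection over z
#'
#' Collapses the z-axis of a stack by the pixelwise maximum, the standard
#' rendering for cortical myosin recordings.
#'
#' @param stack an [image_stack].
#' @return an [image_stack] with a single z-plane; metadata preserved.
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "image_stack")) abort("`stack` must be an image_stack")
  d <- dim(stack$data)
  if (d[2L] == 1L) return(stack)
  out <- stack$data[, 1L, , , drop = FALSE]
  for (z in 2:d[2L]) out <- pmax(out, stack$data[, z, , , drop = FALSE])
  image_stack(array(out, c(d[1L], 1L, d[3L], d[4L])),
              stack$frame_interval, stack$pixel_size, stack$z_spacing)
}

#' Superimpose consecutive frames
#'
#' Pixelwise maximum over `k` consecutive frames starting at `t0`, used to
#' visualize streams of moving contractile foci in a single still.
#'
#' @param stack an [image_stack]; z is max-projected first if present.
#' @param t0 first frame (0-based).
#' @param k number of frames to combine (default 5).
#' @return a Y x X numeric matrix.
#' @export
superimpose <- function(stack, t0 = 0, k = 5) {
  t0 <- check_count(t0, "t0", min = 0L)
  k <- check_count(k, "k", min = 1L)
  if (t0 + k > n_frames(stack))
    abort(sprintf("frames %d..%d exceed stack length %d",
                  t0, t0 + k - 1L, n_frames(stack)))
  out <- frame_matrix(stack, t0)
  if (k > 1L) for (t in (t0 + 1L):(t0 + k - 1L))
    out <- pmax(out, frame_matrix(stack, t))
  out
}
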