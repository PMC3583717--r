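#' Intensity and extension traces
#'
#' Paired time series of integrated local contraction intensity and
#' extension-tip position, sampled on a strictly increasing, uniformly spaced
#' time grid.
#'
#' @param times sample times, seconds (uniform spacing).
#' @param values integrated intensity, AU.
#' @param normalized logical flag; a normalized intensity trace has maximum 1.
#' @return data frame of class `intensity_trace` / `extension_trace` with
#'   columns `time_s` and `intensity_au` / `tip_um`.
#' @export
intensity_trace <- function(times, values, normalized = FALSE) {
  check_time_grid(times)
  if (length(values) != length(times)) abort("times and values differ in length")
  structure(data.frame(time_s = times, intensity_au = values),
            normalized = normalized,
            class = c("intensity_trace", "data.frame"))
}

#' @rdname intensity_trace
#' @param tip tip position, micrometres (or fraction of the final position if
#'   normalized, in which case the final value is 1).
#' @export
extension_trace <- function(times, tip, normalized = FALSE) {
  check_time_grid(times)
  if (length(tip) != length(times)) abort("times and tip differ in length")
  structure(data.frame(time_s = times, tip_um = tip),
            normalized = normalized,
            class = c("extension_trace", "data.frame"))
}

check_time_grid <- function(times) {
  if (length(times) < 2L) abort("a trace needs at least two samples")
  dt <- diff(times)
  if (any(dt <= 0)) abort("trace times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    abort("trace times must be uniformly spaced")
  invisible(times)
}

trace_dt <- function(trace) trace$time_s[2L] - trace$time_s[1L]

#' Normalize a coupled trace pair
#'
#' Applies the display conventions of the contraction/extension analysis:
#' intensity is divided by its maximal integrated value, and extension
#' advancement is divided by the final position of the tip (so the last value
#' is 1).
#'
#' @param intensity an [intensity_trace].
#' @param extension an [extension_trace].
#' @return list with normalized `intensity` and `extension` traces.
#' @export
normalize_traces <- function(intensity, extension) {
  if (!inherits(intensity, "intensity_trace") ||
      !inherits(extension, "extension_trace"))
    abort("`intensity`/`extension` must be intensity_trace / extension_trace")
  mx <- max(intensity$intensity_au)
  if (mx <= 0) abort("maximal intensity must be > 0")
  tip <- extension$tip_um
  fin <- tip[length(tip)]
  if (abs(fin - tip[1L]) < .Machine$double.eps * max(1, abs(fin)))
    abort("constant extension trace: final-position normalization undefined")
  if (abs(fin) < .Machine$double.eps)
    abort("final tip position is zero: normalization undefined")
  list(intensity = intensity_trace(intensity$time_s,
                                   intensity$intensity_au / mx,
                                   normalized = TRUE),
       extension = extension_trace(extension$time_s, tip / fin,
                                   normalized = TRUE))
}

#' Time-lagged correlation scan of extension against intensity
#'
#' For every lag in `lags`, the extension-tip position at time `t` is
#' regressed (ordinary least squares) on the intensity at `t - lag` over the
#' overlapping window, and the coefficient of determination r-squared (the
#' square of the Pearson correlation) is recorded.  The peak lag is the
#' argmax, with ties broken toward the smaller lag.  Lags that are not
#' multiples of the sampling interval are evaluated by linear interpolation
#' of the intensity trace.  Negative lags (extension leading intensity) are
#' excluded by default and can be enabled to check that reversed lags score
#' worse.
#'
#' @param intensity an [intensity_trace].
#' @param extension an [extension_trace] on the same time grid.
#' @param lags lag grid in seconds (default 0 to 60 s in sampling-interval
#'   steps).
#' @param min_overlap minimum number of overlapping samples per lag.
#' @param allow_negative permit negative lags in `lags`.
#' @return object of class `lag_scan`: list with `lags`, `r_squared`,
#'   `peak_lag`, `peak_r2`.
#' @export
lag_scan <- function(intensity, extension, lags = NULL, min_overlap = 10,
                     allow_negative = FALSE) {
  if (!inherits(intensity, "intensity_trace") ||
      !inherits(extension, "extension_trace"))
    abort("`intensity`/`extension` must be intensity_trace / extension_trace")
  dt_i <- trace_dt(intensity); dt_e <- trace_dt(extension)
  if (abs(dt_i - dt_e) > 1e-9) abort("traces must share one sampling interval")
  if (!isTRUE(all.equal(intensity$time_s, extension$time_s)))
    abort("traces must share one time grid")
  lags <- lags %||% seq(0, 60, by = dt_i)
  lags <- sort(lags)
  if (!allow_negative && any(lags < 0))
    abort("negative lags require allow_negative = TRUE")
  tt <- intensity$time_s
  r2 <- vapply(lags, function(lag) {
    src <- tt - lag
    ok <- src >= tt[1L] & src <= tt[length(tt)]
    if (sum(ok) < min_overlap)
      abort(sprintf(
        "overlap of %d samples at lag %g s is below the minimum of %d",
        sum(ok), lag, min_overlap))
    x <- stats::approx(tt, intensity$intensity_au, xout = src[ok])$y
    y <- extension$tip_um[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)^2
  }, numeric(1))
  peak <- which.max(r2)
  structure(list(lags = lags, r_squared = r2,
                 peak_lag = lags[peak], peak_r2 = r2[peak]),
            class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  cat(sprintf("lag_scan: peak r^2 = %.3f at lag %g s (%d lags scanned)\n",
              x$peak_r2, x$peak_lag, length(x$lags)))
  invisible(x)
}

#' @export
as.data.frame.lag_scan <- function(x, ...) {
  data.frame(lag_s = x$lags, r_squared = x$r_squared)
}

#' Extension-tip trace from outline series
#'
#' The tip position at each frame is the maximal extent of the extension
#' outline along a given direction (micrometres).
#'
#' @param outlines data frame `frame, x, y` (micrometres), one polygon per
#'   frame; optional `time_s` column.
#' @param direction 2D advance direction (need not be unit length).
#' @param frame_interval seconds per frame when `time_s` is absent.
#' @return an [extension_trace].
#' @export
advancement_from_outlines <- function(outlines, direction = c(1, 0),
                                      frame_interval = 2) {
  if (!all(c("frame", "x", "y") %in% names(outlines)))
    abort("`outlines` needs columns frame, x, y")
  frames <- sort(unique(outlines$frame))
  if (length(frames) < 2L) abort("need outlines for at least two frames")
  tip <- vapply(frames, function(f) {
    p <- outlines[outlines$frame == f, c("x", "y")]
    if (nrow(p) == 0L) abort(sprintf("empty outline at frame %g", f))
    poly_extent(p, direction)[2L]
  }, numeric(1))
  times <- if (!is.null(outlines$time_s))
    vapply(frames, function(f)
      outlines$time_s[outlines$frame == f][1L], numeric(1))
  else frames * frame_interval
  extension_trace(times, tip)
}
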