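#' Circumferential stretch factor of a coplanar division
#'
#' Geometric model of how one symmetric, coplanar cell division spreads a
#' tissue around the transverse circumference.  The cell footprint (a unit
#' circle in the surface plane) is stretched two-fold along the spindle,
#' which lies at angle `theta` to the A-P axis, while thickness halves
#' (volume conserved; the surface cells cycle cuboidal to columnar and back).
#' The circumferential semi-axis of the stretched footprint is
#' `g(theta) = sqrt(4 sin^2 theta + cos^2 theta)`, the factor by which the
#' tissue's circumferential extent grows per division round.  This closed
#' form is a reconstruction of the published calculation, which states its
#' assumptions (perfect symmetry, measured division timings, mean spindle
#' angle 36 degrees) but not its formula; the polygon-stretching oracle in
#' the test suite checks it independently.
#'
#' `g` is monotone on 0-90 degrees with `g(0) = 1` (purely A-P division, no
#' circumferential growth) and `g(90) = 2` (purely circumferential doubling).
#'
#' @param theta_deg spindle angle(s) to the A-P axis, degrees; angles outside
#'   0-90 are folded into that range.
#' @return stretch factor(s), dimensionless.
#' @export
spread_factor <- function(theta_deg) {
  if (!is.numeric(theta_deg) || any(!is.finite(theta_deg)))
    abort("`theta_deg` must be finite numeric")
  th <- fold_angle(theta_deg) * pi / 180
  sqrt(4 * sin(th)^2 + cos(th)^2)
}

normalize_interval <- function(lo, hi) {
  ## map an angular interval onto [0, 360), splitting at the wrap point
  if (hi < lo) abort("interval end before start")
  w <- hi - lo
  if (w >= 360) return(cbind(0, 360))
  lo <- lo %% 360; hi2 <- lo + w  # preserve width
  if (hi2 <= 360) cbind(lo, hi2)
  else rbind(cbind(lo, 360), cbind(0, hi2 - 360))
}

#' Measured circumferential spread of a tissue
#'
#' Sums the angular extent of every cross-section interval carrying the
#' requested tissue label (both lateral halves are added), divides by 360
#' degrees, and scales to percent of the whole circumference.  Overlapping
#' same-tissue intervals are merged with a warning; a timepoint with no
#' interval for the tissue scores 0 percent with a warning.  When several
#' embryos are present the per-timepoint mean and SD across embryos are
#' reported.
#'
#' @param sections data frame `time_s, tissue, theta_start_deg,
#'   theta_end_deg` with an optional `embryo` column.
#' @param tissue tissue label to measure (e.g. `"AB"`).
#' @return data frame of class `spread_series`: `time_s, spread_pct, sd_pct,
#'   n_embryos`.
#' @export
measured_spread <- function(sections, tissue) {
  need <- c("time_s", "tissue", "theta_start_deg", "theta_end_deg")
  if (!all(need %in% names(sections)))
    abort(paste("`sections` needs columns", paste(need, collapse = ", ")))
  if (is.null(sections$embryo)) sections$embryo <- 1L
  times <- sort(unique(sections$time_s))
  embryos <- unique(sections$embryo)
  per <- matrix(NA_real_, length(times), length(embryos),
                dimnames = list(NULL, as.character(embryos)))
  warned_overlap <- FALSE; warned_absent <- FALSE
  for (ei in seq_along(embryos)) for (ti in seq_along(times)) {
    sub <- sections[sections$embryo == embryos[ei] &
                      sections$time_s == times[ti], , drop = FALSE]
    if (!nrow(sub)) next
    hit <- sub[sub$tissue == tissue, , drop = FALSE]
    if (!nrow(hit)) {
      if (!warned_absent) {
        warning(sprintf("tissue '%s' absent at some timepoints: scored 0%%",
                        tissue), call. = FALSE)
        warned_absent <- TRUE
      }
      per[ti, ei] <- 0
      next
    }
    iv <- do.call(rbind, mapply(normalize_interval, hit$theta_start_deg,
                                hit$theta_end_deg, SIMPLIFY = FALSE))
    raw <- sum(iv[, 2L] - iv[, 1L])
    merged <- interval_union(iv)
    tot <- interval_length(merged)
    if (tot < raw - 1e-9 && !warned_overlap) {
      warning("overlapping same-tissue intervals merged", call. = FALSE)
      warned_overlap <- TRUE
    }
    per[ti, ei] <- tot / 360 * 100
  }
  out <- data.frame(
    time_s = times,
    spread_pct = apply(per, 1L, mean, na.rm = TRUE),
    sd_pct = apply(per, 1L, function(v)
      if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else 0),
    n_embryos = apply(per, 1L, function(v) sum(!is.na(v))))
  class(out) <- c("spread_series", "data.frame")
  out
}

#' Theoretical circumferential spread under coplanar divisions
#'
#' Propagates an initial spread through a list of division events under the
#' symmetric coplanar-division model: every division multiplies the dividing
#' cell's circumferential footprint by [spread_factor()] of its spindle
#' angle.  Relative footprint widths are reconstructed from the division list
#' itself (parent names form a binary tree; each division hands each daughter
#' `g(theta) / 2` of the parent's width), so the tissue total at time `t` is
#' the width sum over cells alive at `t`, capped at 100 percent.  When all
#' angles in a synchronized round are equal this reduces to multiplying the
#' tissue spread by `g` once per round.
#'
#' Whether the published curve used per-division measured angles or the
#' 36-degree mean throughout is not stated; both modes are provided.
#'
#' @param initial_spread starting spread, percent of circumference (0-100].
#' @param divisions data frame `parent, time_s, angle_deg`, sorted by time.
#' @param times output time grid, seconds.
#' @param angle_mode `"per-division"` uses each event's angle;
#'   `"mean"` replaces every angle by `mean_angle`.
#' @param mean_angle angle used in `"mean"` mode, degrees (default 36).
#' @return data frame of class `spread_series`: `time_s, spread_pct`.
#' @export
theoretical_spread <- function(initial_spread, divisions, times,
                               angle_mode = c("per-division", "mean"),
                               mean_angle = 36) {
  angle_mode <- match.arg(angle_mode)
  check_number(initial_spread, "initial_spread", min = 1e-12, max = 100)
  if (nrow(divisions) && is.unsorted(divisions$time_s))
    abort("`divisions` must be sorted by time")
  if (nrow(divisions) &&
      any(!is.finite(divisions$angle_deg)))
    abort("division angles must be finite")
  ang <- if (angle_mode == "mean") rep(mean_angle, nrow(divisions))
         else divisions$angle_deg
  if (any(ang < 0 | ang > 90) && angle_mode == "per-division" &&
      any(fold_angle(divisions$angle_deg) != divisions$angle_deg))
    divisions$angle_deg <- fold_angle(divisions$angle_deg)
  ## reconstruct relative widths from the lineage tree:
  ## founders are parents that are nobody's daughter
  all_daughters <- c(paste0(divisions$parent, "a"), paste0(divisions$parent, "p"))
  founders <- unique(divisions$parent[!divisions$parent %in% all_daughters])
  if (nrow(divisions) && !length(founders))
    abort("could not identify founder cells from division parent names")
  width <- if (length(founders))
    stats::setNames(rep(initial_spread / length(founders), length(founders)),
                    founders)
  else c(root = initial_spread)
  spread_at <- function(tt) {
    w <- width
    if (nrow(divisions)) for (i in seq_len(nrow(divisions))) {
      if (divisions$time_s[i] > tt) break
      p <- divisions$parent[i]
      if (!p %in% names(w)) next
      g <- spread_factor(if (angle_mode == "mean") mean_angle
                         else divisions$angle_deg[i])
      half <- w[[p]] * g / 2
      w <- w[names(w) != p]
      w[[paste0(p, "a")]] <- half
      w[[paste0(p, "p")]] <- half
    }
    min(100, sum(unlist(w)))
  }
  times <- sort(times)
  out <- data.frame(time_s = times,
                    spread_pct = vapply(times, spread_at, numeric(1)))
  class(out) <- c("spread_series", "data.frame")
  out
}

#' Compare measured and theoretical spread series
#'
#' Interpolates the theoretical series linearly onto the measured timepoints
#' and reports per-timepoint residuals and their RMS deviation in percentage
#' points.  No hypothesis test is attached: the comparison is a curve
#' overlay.
#'
#' @param measured,theoretical `spread_series` data frames (columns `time_s`,
#'   `spread_pct`).
#' @return list with `residuals` (data frame `time_s, measured_pct,
#'   theoretical_pct, residual_pct`) and `rms_pct`.
#' @export
compare_spread <- function(measured, theoretical) {
  for (s in list(measured, theoretical))
    if (!all(c("time_s", "spread_pct") %in% names(s)))
      abort("spread series need columns time_s and spread_pct")
  lo <- max(min(measured$time_s), min(theoretical$time_s))
  hi <- min(max(measured$time_s), max(theoretical$time_s))
  if (lo > hi) abort("measured and theoretical time ranges do not overlap")
  keep <- measured$time_s >= lo & measured$time_s <= hi
  m <- measured[keep, , drop = FALSE]
  th <- stats::approx(theoretical$time_s, theoretical$spread_pct,
                      xout = m$time_s)$y
  res <- m$spread_pct - th
  list(residuals = data.frame(time_s = m$time_s, measured_pct = m$spread_pct,
                              theoretical_pct = th, residual_pct = res),
       rms_pct = sqrt(mean(res^2)))
}
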