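#' Apical/basolateral axis ratio and flatness of a cell outline
#'
#' The apical axis is the outline's extent along the apical direction; the
#' basolateral axis is the extent along the in-section perpendicular.
#' Flatness is `1 - (shorter extent / longer extent)`, bounded in \[0, 1\]
#' (0 for a square section, approaching 1 for a flat one); this definition
#' is printed in every output header because the original formula is cited
#' to a reference and not reproduced in the text, so the implementation here
#' is auditable rather than authoritative.
#'
#' @param outline polygon (matrix or data frame with `x`, `y`), micrometres.
#' @param apical_direction 2D direction of the apical axis.
#' @param time_s optional timestamp carried into the result.
#' @return one-row data frame of class `shape_measure`: `time_s, apical_um,
#'   basolateral_um, ratio, flatness`.
#' @export
axis_ratio <- function(outline, apical_direction = c(0, 1), time_s = NA_real_) {
  p <- as_poly(outline, "outline")
  if (!poly_is_simple(p)) abort("`outline` polygon is self-intersecting")
  if (polygon_area(p) <= 0) abort("degenerate outline: zero area")
  d <- as.numeric(apical_direction)
  ap <- diff(poly_extent(p, d))
  bl <- diff(poly_extent(p, c(-d[2L], d[1L])))
  if (ap <= 0 || bl <= 0) abort("degenerate outline: zero extent")
  out <- data.frame(time_s = time_s, apical_um = ap, basolateral_um = bl,
                    ratio = ap / bl, flatness = 1 - min(ap, bl) / max(ap, bl))
  class(out) <- c("shape_measure", "data.frame")
  out
}

#' Polynomial fit of an axis-ratio timecourse
#'
#' Least-squares polynomial (default cubic) of the mean apical/basolateral
#' ratio against time, the summary used for the cuboidal-columnar-cuboidal
#' shape cycle of surface cells.
#'
#' @param measures data frame with columns `time_s` and `ratio` (rows from
#'   [axis_ratio()], possibly several per timepoint).
#' @param degree polynomial degree (default 3).
#' @return list with `coefficients` (intercept first), `residual_sd`,
#'   `fitted` (data frame `time_s, mean_ratio, fit`), and the `lm` fit.
#' @export
fit_ratio_timecourse <- function(measures, degree = 3) {
  degree <- check_count(degree, "degree", min = 0L)
  if (!all(c("time_s", "ratio") %in% names(measures)))
    abort("`measures` needs columns time_s and ratio")
  agg <- stats::aggregate(ratio ~ time_s, data = measures, FUN = mean)
  if (nrow(agg) < degree + 1L)
    abort(sprintf("need at least %d timepoints for degree %d",
                  degree + 1L, degree))
  fit <- if (degree == 0L) stats::lm(ratio ~ 1, data = agg)
         else stats::lm(ratio ~ poly(time_s, degree, raw = TRUE), data = agg)
  if (any(is.na(stats::coef(fit))))
    abort("rank-deficient polynomial design (too few distinct timepoints)")
  list(coefficients = unname(stats::coef(fit)),
       residual_sd = stats::sigma(fit),
       fitted = data.frame(time_s = agg$time_s, mean_ratio = agg$ratio,
                           fit = stats::fitted(fit)),
       fit = fit)
}

#' Fraction of a target outline covered by other outlines
#'
#' `area(target intersected with the union of the covering outlines) /
#' area(target)`, computed by exact polygon decomposition (no rasterization).
#' This is the covering-kinetics measurement for internalizing cells sealed
#' over by the extensions of their neighbours.
#'
#' @param target target polygon (the exposed cell surface).
#' @param covers list of covering polygons (may be empty).
#' @return fraction in \[0, 1\].
#' @export
covering_fraction <- function(target, covers) {
  if (is.data.frame(covers) || is.matrix(covers)) covers <- list(covers)
  tp <- as_poly(target, "target")
  if (!poly_is_simple(tp)) abort("`target` polygon is self-intersecting")
  a <- polygon_area(tp)
  if (a <= 0) abort("degenerate target: zero area")
  min(1, area_in_target(tp, covers) / a)
}

#' Regression of bleb-driven translocation on bleb area
#'
#' Ordinary least squares of the anterior translocation (micrometres) on the
#' maximal cross-sectional bleb area (square micrometres), the relationship
#' used to link cortical rupture size to germline-precursor movement.
#' Unweighted, as the published fit shows a single regression line.
#'
#' @param events data frame with columns `area_um2` and `translocation_um`
#'   (e.g. from [generate_blebs()] or [detect_blebs()], where the columns are
#'   `max_area_um2`; both names are accepted).
#' @return list of class `bleb_fit`: `slope` (um per um^2), `intercept` (um),
#'   `r_squared`, `n`, `slope_se`, and the `lm` fit.
#' @export
bleb_regression <- function(events) {
  area <- events$area_um2 %||% events$max_area_um2
  transl <- events$translocation_um
  if (is.null(area) || is.null(transl))
    abort("`events` needs area (area_um2 or max_area_um2) and translocation_um")
  if (length(area) < 3L) abort("need at least 3 bleb events")
  if (stats::sd(area) == 0) abort("zero variance in bleb area")
  fit <- stats::lm(transl ~ area)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 n = length(area),
                 slope_se = summary(fit)$coefficients[2L, 2L],
                 fit = fit),
            class = "bleb_fit")
}

#' @export
print.bleb_fit <- function(x, ...) {
  cat(sprintf(
    "bleb regression: translocation = %.4f + %.4f x area (um, um^2); r^2 = %.3f, n = %d\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}
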