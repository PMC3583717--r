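## Exact polygon area arithmetic by vertical (trapezoidal) decomposition.
##
## All boolean-area questions in the package (covering fractions, bleb excess
## areas) reduce to the area of (target polygon) intersected with the union of
## other polygons.  The plane is cut into horizontal strips at every vertex y
## and every pairwise edge-crossing y; inside a strip no two edges cross, so
## the union length of the x-intervals varies linearly with y and the strip's
## exact area is (union length at the strip midpoint) x (strip height).

as_poly <- function(p, name = "polygon") {
  if (is.data.frame(p)) p <- cbind(p$x, p$y)
  if (!is.matrix(p) || ncol(p) != 2L)
    abort(sprintf("`%s` must be a two-column matrix or data frame with x, y",
                  name))
  storage.mode(p) <- "double"
  ## drop a repeated closing vertex
  n <- nrow(p)
  if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3L) abort(sprintf("`%s` needs at least 3 distinct vertices", name))
  if (!all(is.finite(p))) abort(sprintf("`%s` has non-finite vertices", name))
  p
}

signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Area of a simple closed polygon
#'
#' Shoelace formula; vertex order (clockwise or anticlockwise) is irrelevant.
#'
#' @param p polygon as a two-column matrix or a data frame with `x`, `y`.
#' @return area in squared input units.
#' @export
polygon_area <- function(p) abs(signed_area(as_poly(p)))

#' Centroid of a simple closed polygon
#'
#' @inheritParams polygon_area
#' @return length-2 numeric vector `c(x, y)`.
#' @export
polygon_centroid <- function(p) {
  p <- as_poly(p)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) abort("degenerate polygon: zero area")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

## does the closed segment p1-p2 properly cross q1-q2 (shared endpoints ignored)?
segments_cross_y <- function(p1, p2, q1, q2) {
  r <- p2 - p1; s <- q2 - q1
  denom <- r[1L] * s[2L] - r[2L] * s[1L]
  if (abs(denom) < 1e-300) return(NULL)
  qp <- q1 - p1
  t <- (qp[1L] * s[2L] - qp[2L] * s[1L]) / denom
  u <- (qp[1L] * r[2L] - qp[2L] * r[1L]) / denom
  eps <- 1e-12
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1[2L] + t * r[2L]
}

poly_edges <- function(p) {
  n <- nrow(p)
  cbind(p, p[c(2:n, 1L), , drop = FALSE])  # x1 y1 x2 y2
}

## x-intervals of the polygon interior on the horizontal line y = h
## (even-odd rule; h must avoid vertex ys, which strip midpoints guarantee)
poly_xintervals <- function(p, h) {
  y1 <- p[, 2L]; y2 <- c(y1[-1L], y1[1L])
  x1 <- p[, 1L]; x2 <- c(x1[-1L], x1[1L])
  cross <- (y1 < h) != (y2 < h)
  if (!any(cross)) return(NULL)
  xs <- x1[cross] + (h - y1[cross]) / (y2[cross] - y1[cross]) *
    (x2[cross] - x1[cross])
  xs <- sort(xs)
  matrix(xs, ncol = 2L, byrow = TRUE)
}

interval_union <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(NULL)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    k <- nrow(out)
    if (m[i, 1L] <= out[k, 2L]) out[k, 2L] <- max(out[k, 2L], m[i, 2L])
    else out <- rbind(out, m[i, ])
  }
  out
}

interval_intersect <- function(a, b) {
  if (is.null(a) || is.null(b)) return(NULL)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L]); hi <- pmin(a[i, 2L], b[, 2L])
    keep <- hi > lo
    if (any(keep)) out <- rbind(out, cbind(lo[keep], hi[keep]))
  }
  out
}

interval_length <- function(m) if (is.null(m)) 0 else sum(m[, 2L] - m[, 1L])

## exact area of target ∩ (union of covers); covers may be an empty list
area_in_target <- function(target, covers) {
  target <- as_poly(target, "target")
  covers <- lapply(covers, as_poly, name = "covering outline")
  if (length(covers) == 0L) return(0)
  polys <- c(list(target), covers)
  ys <- unlist(lapply(polys, function(p) p[, 2L]))
  ## pairwise edge crossings between different polygons
  edges <- lapply(polys, poly_edges)
  np <- length(polys)
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    ei <- edges[[i]]; ej <- edges[[j]]
    for (a in seq_len(nrow(ei))) for (b in seq_len(nrow(ej))) {
      h <- segments_cross_y(ei[a, 1:2], ei[a, 3:4], ej[b, 1:2], ej[b, 3:4])
      if (!is.null(h)) ys <- c(ys, h)
    }
  }
  ty <- range(target[, 2L])
  ys <- sort(unique(ys[ys >= ty[1L] & ys <= ty[2L]]))
  area <- 0
  for (k in seq_len(length(ys) - 1L)) {
    hgt <- ys[k + 1L] - ys[k]
    if (hgt < 1e-13) next
    h <- (ys[k] + ys[k + 1L]) / 2
    ti <- poly_xintervals(target, h)
    if (is.null(ti)) next
    ci <- interval_union(do.call(rbind, lapply(covers, poly_xintervals, h = h)))
    area <- area + interval_length(interval_intersect(ti, ci)) * hgt
  }
  area
}

## min/max extent of the polygon's vertex projections on a direction
poly_extent <- function(p, direction) {
  p <- as_poly(p)
  d <- as.numeric(direction)
  nd <- sqrt(sum(d^2))
  if (length(d) != 2L || nd < .Machine$double.eps)
    abort("`direction` must be a non-zero 2D vector")
  range(p %*% (d / nd))
}

## simplicity check used by outline validation (O(n^2), outlines are small)
poly_is_simple <- function(p) {
  p <- as_poly(p)
  e <- poly_edges(p)
  n <- nrow(e)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (b == a + 1L || (a == 1L && b == n)) next  # adjacent edges
    if (!is.null(segments_cross_y(e[a, 1:2], e[a, 3:4], e[b, 1:2], e[b, 3:4])))
      return(FALSE)
  }
  TRUE
}
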