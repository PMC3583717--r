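## Independent brute-force oracles.  Each is deliberately written as plain
## loops / direct formulas, sharing no code with the package implementation.

oracle_max_project <- function(arr4) {
  d <- dim(arr4)
  out <- array(0, c(d[1], 1, d[3], d[4]))
  for (t in 1:d[1]) for (y in 1:d[3]) for (x in 1:d[4]) {
    m <- arr4[t, 1, y, x]
    if (d[2] > 1) for (z in 2:d[2]) if (arr4[t, z, y, x] > m) m <- arr4[t, z, y, x]
    out[t, 1, y, x] <- m
  }
  out
}

## scalar bilinear interpolation at 0-based pixel-centered (x, y),
## written in the standard 4-corner-weight form
oracle_bilinear <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- min(max(x, 0), nx - 1); y <- min(max(y, 0), ny - 1)
  x0 <- min(floor(x), max(nx - 2, 0)); y0 <- min(floor(y), max(ny - 2, 0))
  fx <- x - x0; fy <- y - y0
  v00 <- img[y0 + 1, x0 + 1]
  v01 <- img[y0 + 1, min(x0 + 2, nx)]
  v10 <- img[min(y0 + 2, ny), x0 + 1]
  v11 <- img[min(y0 + 2, ny), min(x0 + 2, nx)]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

oracle_line_profile <- function(img, p0, p1, n_lines, spacing, pixel_size) {
  len <- sqrt(sum((p1 - p0)^2))
  u <- (p1 - p0) / len
  nrm <- c(-u[2], u[1])
  offs <- if (n_lines %% 2 == 0) spacing * (0:(n_lines - 1))
          else spacing * ((0:(n_lines - 1)) - (n_lines - 1) / 2)
  s <- 0:floor(len)
  mean_v <- sd_v <- numeric(length(s))
  for (i in seq_along(s)) {
    vals <- numeric(n_lines)
    for (j in seq_along(offs)) {
      px <- p0[1] + s[i] * u[1] + offs[j] * nrm[1]
      py <- p0[2] + s[i] * u[2] + offs[j] * nrm[2]
      vals[j] <- oracle_bilinear(img, px, py)
    }
    mean_v[i] <- mean(vals)
    sd_v[i] <- if (n_lines > 1) sd(vals) else 0
  }
  data.frame(position_um = s * pixel_size, mean = mean_v, sd = sd_v)
}

## even-odd ray-casting point-in-polygon (vectorized over points)
oracle_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in 1:n) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

oracle_mc_covering <- function(target, covers, n = 1e5) {
  bb <- apply(target, 2, range)
  px <- runif(n, bb[1, 1], bb[2, 1])
  py <- runif(n, bb[1, 2], bb[2, 2])
  keep <- oracle_in_polygon(px, py, target)
  px <- px[keep]; py <- py[keep]
  if (!length(px)) return(0)
  covered <- rep(FALSE, length(px))
  for (cv in covers) covered <- covered | oracle_in_polygon(px, py, cv)
  mean(covered)
}

## angular rasterization oracle for the measured circumferential spread
oracle_raster_spread <- function(starts, ends, res = 0.1) {
  grid <- seq(res / 2, 360 - res / 2, by = res)
  hit <- rep(FALSE, length(grid))
  for (k in seq_along(starts)) {
    a <- starts[k] %% 360
    w <- ends[k] - starts[k]
    b <- a + w
    if (b <= 360) hit <- hit | (grid >= a & grid < b)
    else hit <- hit | (grid >= a) | (grid < b - 360)
  }
  mean(hit) * 100
}

oracle_moving_average <- function(v, window) {
  h <- (window - 1) / 2
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    lo <- max(1, i - h); hi <- min(length(v), i + h)
    out[i] <- sum(v[lo:hi]) / (hi - lo + 1)
  }
  out
}

## Pearson correlation of z-increments over shared times, by direct formula
oracle_lr_cor <- function(a, b) {
  shared <- intersect(a$t, b$t)
  za <- diff(a$z[match(shared, a$t)])
  zb <- diff(b$z[match(shared, b$t)])
  ma <- mean(za); mb <- mean(zb)
  sum((za - ma) * (zb - mb)) /
    sqrt(sum((za - ma)^2) * sum((zb - mb)^2))
}

## polygon oracle for the coplanar-division stretch factor: stretch a dense
## unit-circle footprint 2x along the spindle direction and measure the
## half-extent of its projection on the circumferential axis
oracle_stretch_factor <- function(theta_deg) {
  th <- theta_deg * pi / 180
  a <- seq(0, 2 * pi, length.out = 20001)
  circ <- cbind(cos(a), sin(a))
  spindle <- c(cos(th), sin(th))     # x = A-P, y = circumferential
  perp <- c(-sin(th), cos(th))
  along <- circ %*% spindle
  across <- circ %*% perp
  stretched <- outer(2 * as.vector(along), spindle) +
    outer(as.vector(across), perp)
  max(stretched[, 2])                 # circumferential semi-axis
}

## random star-shaped (simple) polygon for randomized geometry instances
random_polygon <- function(n = 8, r_range = c(1, 3), center = c(0, 0)) {
  ang <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, r_range[1], r_range[2])
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}

random_convex_polygon <- function(n = 8, r = 2, center = c(0, 0)) {
  ang <- sort(runif(n, 0, 2 * pi))
  cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
}
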