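test_that("normalization follows the max-intensity / final-tip conventions", {
  it <- intensity_trace(c(0, 2, 4), c(2, 4, 8))
  et <- extension_trace(c(0, 2, 4), c(3, 9, 12))
  nt <- normalize_traces(it, et)
  expect_equal(nt$intensity$intensity_au, c(0.25, 0.5, 1))
  expect_equal(nt$extension$tip_um[3], 1)
  expect_true(attr(nt$intensity, "normalized"))
  ## a constant extension has no final-position scale
  expect_error(normalize_traces(it, extension_trace(c(0, 2, 4), c(5, 5, 5))),
               "constant extension")
})

test_that("trace constructors enforce the uniform time grid", {
  expect_error(intensity_trace(c(0, 1, 1.5), 1:3), "uniformly spaced")
  expect_error(intensity_trace(c(0, -1, -2), 1:3), "strictly increasing")
})

test_that("lag scan recovers exact constructed shifts", {
  tt <- seq(0, 198, by = 2)
  set.seed(14)
  v <- cumsum(rnorm(length(tt)))^2
  ## extension identical to intensity: peak at lag 0 with r^2 = 1
  sc0 <- lag_scan(intensity_trace(tt, v), extension_trace(tt, v))
  expect_equal(sc0$peak_lag, 0)
  expect_equal(sc0$peak_r2, 1, tolerance = 1e-12)
  ## extension equal to intensity shifted by exactly 5 samples
  e <- c(rep(v[1], 5), v[1:(length(v) - 5)])
  sc5 <- lag_scan(intensity_trace(tt, v), extension_trace(tt, e))
  expect_equal(sc5$peak_lag, 10)            # 5 samples x 2 s
  expect_equal(sc5$peak_r2, 1, tolerance = 1e-9)
})

test_that("lag scan agrees with an independent per-lag refit", {
  tr <- generate_coupled_traces(synth_config(seed = 42))
  nt <- normalize_traces(tr$intensity, tr$extension)
  sc <- lag_scan(nt$intensity, nt$extension)
  tt <- nt$intensity$time_s
  for (lag in seq(0, 60, by = 2)) {
    k <- lag / 2
    n <- length(tt)
    x <- nt$intensity$intensity_au[1:(n - k)]
    y <- nt$extension$tip_um[(k + 1):n]
    r2 <- summary(lm(y ~ x))$r.squared
    expect_equal(sc$r_squared[sc$lags == lag], r2, tolerance = 1e-9)
  }
  expect_equal(sc$peak_lag, 20)
  expect_gte(sc$r_squared[sc$lags == 20], 0.9)
})

test_that("r-squared is invariant to affine rescaling of either trace", {
  tr <- generate_coupled_traces(synth_config(seed = 10))
  sc1 <- lag_scan(tr$intensity, tr$extension)
  it2 <- intensity_trace(tr$intensity$time_s,
                         3.7 * tr$intensity$intensity_au + 11)
  et2 <- extension_trace(tr$extension$time_s, 0.2 * tr$extension$tip_um - 4)
  sc2 <- lag_scan(it2, et2)
  expect_equal(sc1$r_squared, sc2$r_squared, tolerance = 1e-9)
  expect_equal(sc1$peak_lag, sc2$peak_lag)
  ## hence it commutes with normalization
  nt <- normalize_traces(tr$intensity, tr$extension)
  sc3 <- lag_scan(nt$intensity, nt$extension)
  expect_equal(sc1$r_squared, sc3$r_squared, tolerance = 1e-9)
})

test_that("reversed lags score worse than the causal direction", {
  tr <- generate_coupled_traces(synth_config(seed = 42))
  sc <- lag_scan(tr$intensity, tr$extension, lags = seq(-40, 60, by = 2),
                 allow_negative = TRUE)
  expect_equal(sc$peak_lag, 20)
  neg <- sc$r_squared[sc$lags < 0]
  expect_true(all(neg < sc$peak_r2))
  expect_error(lag_scan(tr$intensity, tr$extension, lags = c(-10, 0, 10)),
               "allow_negative")
})

test_that("overlap shorter than the minimum is an informative error", {
  tt <- seq(0, 38, by = 2)
  it <- intensity_trace(tt, seq_along(tt))
  et <- extension_trace(tt, seq_along(tt))
  expect_error(lag_scan(it, et, lags = c(0, 36)), "minimum")
})

test_that("median peak lag over replicates equals the generating 20 s delay", {
  lags <- vapply(1:25, function(s) {
    tr <- generate_coupled_traces(synth_config(seed = s))
    lag_scan(tr$intensity, tr$extension)$peak_lag
  }, numeric(1))
  expect_equal(median(lags), 20)
  ## the central spread stays within one sampling interval per side
  expect_lte(diff(quantile(lags, c(0.05, 0.95))), 4)
})

test_that("tip advancement from outlines is the directional extent", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  ## static outline: constant trace
  still <- do.call(rbind, lapply(0:4, function(f)
    data.frame(frame = f, x = sq[, 1], y = sq[, 2])))
  tr0 <- advancement_from_outlines(still, c(1, 0))
  expect_true(all(tr0$tip_um == 2))
  ## square translated 1 um/frame: slope 1 per frame
  mov <- do.call(rbind, lapply(0:4, function(f)
    data.frame(frame = f, x = sq[, 1] + f, y = sq[, 2])))
  tr1 <- advancement_from_outlines(mov, c(1, 0), frame_interval = 1)
  expect_equal(unname(diff(tr1$tip_um)), rep(1, 4))
  ## invariance under co-rotated coordinates
  th <- 0.7
  rot <- function(p) cbind(cos(th) * p[, 1] - sin(th) * p[, 2],
                           sin(th) * p[, 1] + cos(th) * p[, 2])
  movr <- mov
  movr[, c("x", "y")] <- rot(as.matrix(mov[, c("x", "y")]))
  tr2 <- advancement_from_outlines(movr, c(cos(th), sin(th)),
                                   frame_interval = 1)
  expect_equal(tr2$tip_um, tr1$tip_um, tolerance = 1e-9)
})
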