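make_stack <- function(arr, dt = 2, px = 0.1) image_stack(arr, dt, px)
frame_matrix_of <- function(s, t) rosettes:::frame_matrix(s, t)

test_that("max projection is the elementwise maximum and is idempotent", {
  ## z = 1 passes through unchanged
  a1 <- array(runif(2 * 5 * 6), c(2, 5, 6))
  s1 <- make_stack(a1)
  expect_identical(max_project(s1)$data, s1$data)
  ## two constant planes
  a2 <- array(0, c(1, 2, 4, 4)); a2[, 1, , ] <- 3; a2[, 2, , ] <- 5
  expect_true(all(max_project(image_stack(a2, 2, 0.1))$data == 5))
  ## random 4-plane stack against the loop oracle
  set.seed(0)
  a4 <- array(runif(3 * 4 * 7 * 8), c(3, 4, 7, 8))
  s4 <- image_stack(a4, 2, 0.1)
  expect_equal(max_project(s4)$data, oracle_max_project(a4))
  expect_equal(max_project(max_project(s4))$data, max_project(s4)$data)
})

test_that("line profile handles constant and two-row forced cases", {
  img <- array(7, c(1, 10, 12))
  pr <- line_profile(make_stack(img), 0, c(1, 4, 10, 4))
  expect_true(all(pr$mean == 7))
  expect_true(all(pr$sd == 0))
  ## rows y=3 and y=4 are constants 4 and 8; even n_lines starts on the
  ## requested line and steps one pixel to +y
  img2 <- array(0, c(1, 10, 12))
  img2[1, 4, ] <- 4; img2[1, 5, ] <- 8
  pr2 <- line_profile(make_stack(img2), 0, c(1, 3, 10, 3), n_lines = 2)
  expect_true(all(abs(pr2$mean - 6) < 1e-12))
  expect_true(all(abs(pr2$sd - 2 * sqrt(2)) < 1e-12))
})

test_that("line profile peaks at a Gaussian spot center", {
  ny <- 21; nx <- 41
  cx <- 23.4; cy <- 10
  img <- outer(0:(ny - 1), 0:(nx - 1), function(y, x)
    exp(-((x - cx)^2 + (y - cy)^2) / (2 * 2^2)))
  dim(img) <- c(1, ny, nx)
  pr <- line_profile(make_stack(img, px = 0.5), 0, c(2, 10, 38, 10),
                     n_lines = 1)
  peak_x_px <- 2 + (which.max(pr$mean) - 1)   # line starts at x = 2
  expect_lt(abs(peak_x_px - cx), 1)
})

test_that("line profile matches the brute-force sampler on random instances", {
  set.seed(7)
  for (i in 1:50) {
    ny <- sample(8:16, 1); nx <- sample(8:16, 1)
    img <- matrix(runif(ny * nx, 0, 100), ny, nx)
    arr <- array(img, c(1, ny, nx))
    p0 <- c(runif(1, 0, nx - 1), runif(1, 0, ny - 1))
    p1 <- c(runif(1, 0, nx - 1), runif(1, 0, ny - 1))
    if (sum((p1 - p0)^2) < 1) p1 <- pmin(p0 + 2, c(nx - 1, ny - 1))
    nl <- sample(1:3, 1)
    got <- line_profile(make_stack(arr), 0, c(p0, p1), n_lines = nl)
    want <- oracle_line_profile(img, p0, p1, nl, 1, 0.1)
    expect_equal(got$mean, want$mean, tolerance = 1e-9)
    expect_equal(got$sd, want$sd, tolerance = 1e-9)
    expect_equal(got$position_um, want$position_um, tolerance = 1e-12)
  }
})

test_that("out-of-bounds lines are rejected naming the endpoint", {
  s <- make_stack(array(0, c(2, 8, 8)))
  expect_error(line_profile(s, 0, c(-1, 2, 5, 2)), "endpoint 1")
  expect_error(line_profile(s, 0, c(1, 2, 9, 2)), "endpoint 2")
})

test_that("kymograph rows equal single-line profiles and track a moving spot", {
  set.seed(11)
  nT <- 6; ny <- 9; nx <- 30
  arr <- array(runif(nT * ny * nx), c(nT, ny, nx))
  s <- make_stack(arr)
  line <- c(1, 4, 28, 4)
  ky <- kymograph(s, line)
  for (t in c(0, 3, 5)) {
    pr <- line_profile(s, t, line, n_lines = 1)
    expect_equal(as.numeric(ky$data[t + 1, ]), pr$mean, tolerance = 1e-12)
  }
  ## spot moving 1 px/frame along the line: per-row argmax slope is 1
  arr2 <- array(0, c(10, 9, 30))
  for (t in 0:9) arr2[t + 1, 5, 6 + t] <- 10
  ky2 <- kymograph(make_stack(arr2), c(0, 4, 29, 4))
  amax <- apply(ky2$data, 1, which.max) - 1
  slope <- coef(lm(amax ~ seq_along(amax)))[2]
  expect_equal(unname(slope), 1, tolerance = 1e-9)
  expect_error(kymograph(s, c(3, 3, 3, 3)), "zero length")
  expect_error(kymograph(s, line, frames = integer(0)), "empty frame range")
})

test_that("superimposition is the pixelwise max over k frames", {
  arr <- array(0, c(8, 12, 12))
  for (t in 0:7) arr[t + 1, 3 + t, 3 + t] <- 5
  s <- make_stack(arr)
  expect_equal(superimpose(s, 2, 1), frame_matrix_of(s, 2))
  sup <- superimpose(s, 0, 5)
  ## all five spot footprints are present
  for (t in 0:4) expect_equal(sup[3 + t, 3 + t], 5)
  expect_equal(sum(sup == 5), 5)
  ## over the whole movie it equals the temporal max projection
  supT <- superimpose(s, 0, 8)
  expect_equal(supT, apply(arr, c(2, 3), max))
  expect_error(superimpose(s, 6, 5), "exceed")
  ## constant movie stays constant
  cs <- make_stack(array(2, c(4, 6, 6)))
  expect_true(all(superimpose(cs, 0, 4) == 2))
})
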