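mk_track <- function(t, x = 0, y = 0, z = 0) {
  n <- length(t)
  data.frame(t = t, x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n))
}

test_that("path smoothing is the centered moving average with shrinking ends", {
  tr <- mk_track(1:10, x = 3, y = -1, z = 2)
  expect_equal(smooth_path(tr), tr)
  ## unit impulse spreads as 1/5 over the five covering points
  imp <- mk_track(1:11)
  imp$x[6] <- 1
  sm <- smooth_path(imp, 5)
  expect_equal(sm$x[4:8], rep(0.2, 5))
  expect_equal(sm$x[c(1:3, 9:11)], rep(0, 6))
  ## random path equals the loop oracle
  set.seed(5)
  rnd <- mk_track(1:40, x = cumsum(rnorm(40)), y = cumsum(rnorm(40)),
                  z = cumsum(rnorm(40)))
  sm2 <- smooth_path(rnd, 5)
  expect_equal(sm2$x, oracle_moving_average(rnd$x, 5), tolerance = 1e-12)
  expect_equal(sm2$z, oracle_moving_average(rnd$z, 5), tolerance = 1e-12)
  expect_identical(sm2$t, rnd$t)
  expect_error(smooth_path(mk_track(1:3), 5), "exceeds")
  expect_error(smooth_path(rnd, 4), "odd")
})

test_that("L/R correlation has the expected fixed points and null behaviour", {
  set.seed(9)
  a <- mk_track(1:200, z = cumsum(rnorm(200)))
  expect_equal(lr_correlation(a, a), 1)
  mir <- a; mir$z <- -a$z
  expect_equal(lr_correlation(a, mir), -1)
  b <- mk_track(1:200, z = cumsum(rnorm(200)))
  expect_lt(abs(lr_correlation(a, b)), 0.2)
  expect_equal(lr_correlation(a, b), oracle_lr_cor(a, b), tolerance = 1e-12)
  ## too-short overlap gives the NA sentinel
  short <- mk_track(1:2, z = c(0, 1))
  expect_true(is.na(lr_correlation(short, short)))
})

test_that("correlation is invariant to translation and positive scaling", {
  set.seed(15)
  a <- mk_track(1:50, z = cumsum(rnorm(50)))
  b <- mk_track(1:50, z = cumsum(rnorm(50)))
  r <- lr_correlation(a, b)
  a2 <- a; a2$z <- 5 * a$z + 100
  b2 <- b; b2$z <- 0.3 * b$z - 7
  expect_equal(lr_correlation(a2, b2), r, tolerance = 1e-12)
})

test_that("correlation matrix is symmetric with unit diagonal and exact trivia", {
  set.seed(3)
  base <- cumsum(rnorm(30))
  tracks <- rbind(
    cbind(cell = "ABpla", mk_track(1:30, z = base)),
    cbind(cell = "ABpra", mk_track(1:30, z = -base)),
    cbind(cell = "ABplp", mk_track(1:30, z = base)))
  cm <- correlation_matrix(tracks)
  expect_equal(unclass(cm),
               matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3,
                      dimnames = list(unique(tracks$cell),
                                      unique(tracks$cell))),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(cm)))
  expect_true(all(diag(cm) == 1))
  expect_true(all(abs(cm) <= 1 + 1e-12))
})

test_that("bilateral generator shows within-side coherence and cross-side anti-correlation", {
  bi <- generate_bilateral_tracks(synth_config(seed = 20))
  cm <- correlation_matrix(bi)
  cells <- rownames(cm)
  left <- grepl("^ABpl", cells); right <- grepl("^ABpr", cells)
  within <- c(cm[left, left][upper.tri(cm[left, left])],
              cm[right, right][upper.tri(cm[right, right])])
  across <- cm[left, right]
  expect_gt(mean(within), 0)
  expect_lt(mean(across), 0)
})

test_that("smoothing before correlating raises within-side coherence", {
  ## heavy independent per-cell noise over a long recording: the shared
  ## convergence drift survives the moving average, the noise does not
  bi <- generate_bilateral_tracks(synth_config(seed = 31), n_steps = 200,
                                  track_noise_sd = 1, coherent_sd = 0)
  raw <- correlation_matrix(bi)
  sm <- correlation_matrix(smooth_paths(bi))
  cells <- rownames(raw)
  within_mean <- function(m) {
    left <- grepl("^ABpl", cells); right <- grepl("^ABpr", cells)
    mean(c(m[left, left][upper.tri(m[left, left])],
           m[right, right][upper.tri(m[right, right])]))
  }
  expect_gt(within_mean(sm), within_mean(raw))
})

test_that("displacement metrics project onto the axis in percent of length", {
  tr <- mk_track(0:10)
  expect_equal(displacement_metrics(tr, embryo_length = 50), 0)
  mv <- mk_track(0:10, x = seq(0, 5, length.out = 11))
  expect_equal(displacement_metrics(mv, embryo_length = 50), 10)
  ## scripted 11 % anterior drift of the right side
  bi <- generate_bilateral_tracks(synth_config(seed = 2),
                                  posterior_offset0 = 0.11 * 50,
                                  track_noise_sd = 0, coherent_sd = 0)
  r1 <- bi[bi$cell == bi$cell[grepl("^ABpr", bi$cell)][1], ]
  expect_equal(displacement_metrics(r1, embryo_length = 50), 11,
               tolerance = 0.1 / 11)
  expect_error(displacement_metrics(mv, axis = c(0, 0, 0),
                                    embryo_length = 50), "non-zero")
})

test_that("midline angle is zero for mirrored groups and signed for shifts", {
  tracks <- rbind(
    cbind(cell = "ABplpaa", mk_track(0:5, x = 1, z = 4)),
    cbind(cell = "ABprpaa", mk_track(0:5, x = 1, z = -4)),
    cbind(cell = "ABplppp", mk_track(0:5, x = -3, z = 6)),
    cbind(cell = "ABprppp", mk_track(0:5, x = -3, z = -6)))
  expect_equal(midline_angle(tracks, 2), 0)
  ## right group uniformly posterior-shifted: positive angle by convention
  shifted <- tracks
  shifted$x[grepl("^ABpr", shifted$cell)] <-
    shifted$x[grepl("^ABpr", shifted$cell)] - 2
  expect_gt(midline_angle(shifted, 2), 0)
  ## unmatched cells are reported by name
  expect_error(midline_angle(tracks[tracks$cell != "ABprpaa", ], 2),
               "ABplpaa")
})

test_that("scripted anterior drift symmetrizes the midline monotonically", {
  bi <- generate_bilateral_tracks(synth_config(seed = 4),
                                  track_noise_sd = 0, coherent_sd = 0)
  ts <- sort(unique(bi$t))
  ang <- vapply(ts, function(tt) midline_angle(bi, tt), numeric(1))
  expect_gt(ang[1], 5)
  expect_lt(ang[length(ang)], 1)
  expect_true(all(diff(ang) < 1e-9))
})
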