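test_that("config validation rejects impossible parameters", {
  expect_error(synth_config(image_shape = c(0, 64)), "image_shape")
  expect_error(synth_config(foci_birth_rate = -1), "foci_birth_rate")
  expect_error(synth_config(coupling_delay = -5), "coupling_delay")
  expect_error(synth_config(bleb_retraction_range = c(60, 30)),
               "bleb_retraction_range")
  expect_error(synth_config(division_times = c(100, 50)), "sorted")
})

test_that("generators are bit-reproducible for a fixed config and seed", {
  cfg <- synth_config(seed = 9, n_frames = 30, image_shape = c(32, 32))
  m1 <- generate_cortex_movie(cfg); m2 <- generate_cortex_movie(cfg)
  expect_identical(m1$stack$data, m2$stack$data)
  expect_identical(m1$truth, m2$truth)
  t1 <- generate_coupled_traces(synth_config(seed = 4))
  t2 <- generate_coupled_traces(synth_config(seed = 4))
  expect_identical(t1$intensity, t2$intensity)
  expect_identical(t1$extension, t2$extension)
  l1 <- generate_lineage(cfg); l2 <- generate_lineage(cfg)
  expect_identical(l1$tracks, l2$tracks)
  b1 <- generate_blebs(cfg); b2 <- generate_blebs(cfg)
  expect_identical(b1, b2)
  ## and the generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(5)
  set.seed(1); invisible(generate_cortex_movie(cfg)); after <- runif(5)
  expect_identical(before, after)
})

test_that("movie with no sources and no noise is identically zero", {
  cfg <- synth_config(seed = 2, n_frames = 5, image_shape = c(24, 24),
                      foci_birth_rate = 0, noise_sd = 0)
  m <- generate_cortex_movie(cfg)
  expect_true(all(m$stack$data == 0))
  expect_equal(nrow(m$truth), 0)
})

test_that("truth-table focus count replays the seeded Poisson stream", {
  cfg <- synth_config(seed = 1, n_frames = 100, foci_birth_rate = 0.5,
                      image_shape = c(64, 64))
  m <- generate_cortex_movie(cfg)
  ## birth counts are the first draws of the generator's stream
  expected <- rosettes:::with_seed(1, sum(rpois(100, 0.5)))
  expect_equal(length(unique(m$truth$id)), expected)
})

test_that("coupled traces obey the exact delayed relationship at zero noise", {
  ## degenerate delay: tip increments proportional to the (unsmoothed,
  ## normalized) intensity at the same frame
  cfg0 <- synth_config(seed = 3, coupling_delay = 0, coupling_tau = 0,
                       noise_sd = 0)
  tr0 <- generate_coupled_traces(cfg0)
  i_norm <- tr0$intensity$intensity_au / max(tr0$intensity$intensity_au)
  expect_equal(tr0$extension$tip_um, cfg0$coupling_gain * i_norm,
               tolerance = 1e-12)
  ## a 20 s delay at 2 s sampling is exactly a 10-frame shift
  cfg <- synth_config(seed = 3, coupling_delay = 20, coupling_tau = 0,
                      noise_sd = 0)
  tr <- generate_coupled_traces(cfg)
  n <- nrow(tr$intensity)
  expect_equal(tr$extension$tip_um[11:n],
               cfg$coupling_gain *
                 (tr$intensity$intensity_au / max(tr$intensity$intensity_au))[1:(n - 10)],
               tolerance = 1e-12)
})

test_that("the default coupled pair carries a 20 s lag signature (seed 42)", {
  tr <- generate_coupled_traces(synth_config(seed = 42))
  sc <- lag_scan(tr$intensity, tr$extension)
  expect_equal(sc$peak_lag, 20)
  expect_gte(sc$peak_r2, 0.9)
})

test_that("traces that are too short for the delay are rejected", {
  expect_error(generate_coupled_traces(
    synth_config(n_frames = 20, coupling_delay = 20)), "too short")
})

test_that("lineage generation follows the binary a/p naming and spindle law", {
  ## zero variance: every division angle is exactly the configured mean
  cfg0 <- synth_config(seed = 5, spindle_angle_sd = 0,
                       division_times = c(100, 200))
  lin0 <- generate_lineage(cfg0)
  expect_true(all(lin0$divisions$angle_deg == 36))
  ## one founder, 3 rounds: 8 terminal cells, 7 divisions
  f <- data.frame(name = "AB", tissue = "AB", theta_start = 100,
                  theta_end = 160, ap = 0)
  lin3 <- generate_lineage(synth_config(seed = 5,
                                        division_times = c(100, 200, 300)),
                           founders = f)
  expect_equal(nrow(lin3$divisions), 7)
  term <- lin3$footprints[!is.finite(lin3$footprints$death_s), ]
  expect_equal(nrow(term), 8)
  expect_setequal(nchar(term$cell), 5)  # AB + three a/p letters
  expect_true(all(grepl("^AB[ap]{3}$", term$cell)))
  ## emitted spindle angles reproduce the configured mean within 3 SE
  cfg64 <- synth_config(seed = 7, spindle_angle_sd = 10,
                        division_times = seq(100, 600, by = 100))
  lin64 <- generate_lineage(cfg64, founders = f)
  ang <- lin64$divisions$angle_deg
  expect_gte(length(ang), 60)
  se <- sd(ang) / sqrt(length(ang))
  expect_lt(abs(mean(ang) - 36), 3 * se)
  expect_error(generate_lineage(cfg64, founders = f[0, ]), "at least one")
})

test_that("bleb series obey the configured law and retraction bounds", {
  expect_equal(nrow(generate_blebs(synth_config(bleb_rate = 0))), 0)
  cfg <- synth_config(seed = 6, bleb_noise_sd = 0, bleb_slope = 0.02,
                      n_frames = 600)
  ev <- generate_blebs(cfg)
  expect_gte(nrow(ev), 3)
  fit <- suppressWarnings(bleb_regression(ev))
  expect_equal(fit$slope, 0.02, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  dur <- ev$retraction_s - ev$onset_s
  expect_true(all(dur >= 30 & dur <= 60))
})
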