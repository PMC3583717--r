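gauss_frame <- function(ny, nx, centers, amp = 100, sigma = 2) {
  img <- matrix(0, ny, nx)
  for (k in seq_len(nrow(centers)))
    img <- img + amp * outer(
      exp(-((0:(ny - 1)) - centers[k, 2])^2 / (2 * sigma^2)),
      exp(-((0:(nx - 1)) - centers[k, 1])^2 / (2 * sigma^2)))
  img
}

test_that("focus detection finds isolated Gaussians and nothing in blank frames", {
  expect_equal(nrow(detect_foci(matrix(0, 20, 20), 10)), 0)
  img <- gauss_frame(31, 31, cbind(14.3, 16.8))
  det <- detect_foci(img, min_intensity = 50)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 14.3), 1)
  expect_lt(abs(det$y - 16.8), 1)
})

test_that("detections on a noiseless synthetic movie match ground truth", {
  cfg <- synth_config(seed = 3, noise_sd = 0, n_frames = 60)
  m <- generate_cortex_movie(cfg)
  det <- detect_foci_stack(m$stack, min_intensity = 20)
  ## every truth focus bright enough to clear the threshold is recovered
  bright <- m$truth[m$truth$amplitude >= 25, ]
  hit <- vapply(seq_len(nrow(bright)), function(i) {
    d <- det[det$frame == bright$frame[i], ]
    nrow(d) > 0 &&
      min((d$x - bright$x[i])^2 + (d$y - bright$y[i])^2) <= 4
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  expect_true(all(hit))  # at zero noise recovery is in fact exact
  ## and every detection corresponds to a truth focus (precision 1)
  any_truth <- m$truth[m$truth$amplitude >= 10, ]
  fp <- vapply(seq_len(nrow(det)), function(i) {
    tt <- any_truth[any_truth$frame == det$frame[i], ]
    !nrow(tt) ||
      min((tt$x - det$x[i])^2 + (tt$y - det$y[i])^2) > 9
  }, logical(1))
  expect_equal(sum(fp), 0)
})

test_that("greedy linking builds the expected tracks", {
  ## one slowly drifting focus: a single track over all frames
  det1 <- data.frame(frame = 0:9, x = 10 + 0.5 * (0:9), y = 5, intensity = 1)
  tr1 <- track_foci(det1, max_link_dist = 2)
  expect_equal(length(unique(tr1$id)), 1)
  expect_equal(nrow(tr1), 10)
  ## two stationary well-separated foci: two tracks, no identity swap
  det2 <- rbind(data.frame(frame = rep(0:9, each = 2),
                           x = rep(c(5, 25), 10), y = 5, intensity = 1))
  tr2 <- track_foci(det2, max_link_dist = 3)
  expect_equal(length(unique(tr2$id)), 2)
  for (id in unique(tr2$id))
    expect_equal(length(unique(tr2$x[tr2$id == id])), 1)
  ## permutation of detections within frames yields the same track set
  set.seed(42)
  det3 <- det2[sample(nrow(det2)), ]
  tr3 <- track_foci(det3, max_link_dist = 3)
  key <- function(tr) sort(vapply(split(tr, tr$id), function(g)
    paste(g$frame, g$x, g$y, collapse = "|"), character(1)))
  expect_identical(key(tr3), key(tr2))
})

test_that("noiseless movie yields exactly one track per true focus", {
  cfg <- synth_config(seed = 3, noise_sd = 0, n_frames = 60)
  m <- generate_cortex_movie(cfg)
  det <- detect_foci_stack(m$stack, min_intensity = 20)
  tr <- track_foci(det, max_link_dist = 4)
  expect_equal(length(unique(tr$id)), length(unique(m$truth$id)))
})

test_that("contraction events are counted from converging intensity pulses", {
  ## a single non-converging flat track produces no events
  flat <- structure(data.frame(id = 1L, frame = 0:20, x = 5, y = 5,
                               intensity = 10),
                    class = c("focus_tracks", "data.frame"))
  expect_equal(nrow(count_contractions(flat, 5, 5)), 0)
  ## two tracks converging to one point with a shared pulse: one event
  fr <- 0:10
  conv <- structure(rbind(
    data.frame(id = 1L, frame = fr, x = 10 - fr * 0.9, y = 10,
               intensity = 50 * sin(pi * fr / 10)^2),
    data.frame(id = 2L, frame = fr, x = 1 + fr * 0.1, y = 10,
               intensity = 50 * sin(pi * fr / 10)^2)),
    class = c("focus_tracks", "data.frame"))
  ev <- count_contractions(conv, cluster_radius = 3, min_gain = 30)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_foci, 2)
  expect_identical(ev$focus_ids, "1;2")
  expect_lte(ev$onset_frame, ev$peak_frame)
})

test_that("scripted convergence events are recovered exactly", {
  cfg <- synth_config(seed = 12, image_shape = c(200, 200))
  tr <- generate_contraction_tracks(cfg, n_events = 12)
  ev <- count_contractions(tr, cluster_radius = 6,
                           min_gain = cfg$foci_intensity)
  expect_equal(nrow(ev), 12)
  expect_true(!is.unsorted(ev$onset_frame))
})

test_that("bleb detection recovers scripted and generated protrusions", {
  ## identical outlines: no events
  sq <- rbind(c(0, 0), c(6, 0), c(6, 6), c(0, 6))
  still <- do.call(rbind, lapply(0:5, function(f)
    data.frame(frame = f, x = sq[, 1], y = sq[, 2])))
  expect_equal(nrow(detect_blebs(still, sq, min_area = 0.5)), 0)
  ## a 4 um^2 square bump (2 x 2) appearing then vanishing: one event
  bump <- rbind(c(0, 0), c(6, 0), c(6, 2), c(8, 2), c(8, 4), c(6, 4), c(6, 6),
                c(0, 6))
  series <- rbind(
    data.frame(frame = 0, x = sq[, 1], y = sq[, 2]),
    data.frame(frame = 1, x = bump[, 1], y = bump[, 2]),
    data.frame(frame = 2, x = sq[, 1], y = sq[, 2]))
  ev <- detect_blebs(series, sq, min_area = 1, frame_interval = 2,
                     align = "none")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$max_area_um2, 4, tolerance = 1e-9)
  ## generator round trip: per-event max area within 5 % of truth
  cfg <- synth_config(seed = 8, bleb_noise_sd = 0, n_frames = 200)
  truth <- generate_blebs(cfg)
  scene <- render_bleb_outlines(truth, cfg)
  got <- detect_blebs(scene$outlines, scene$baseline, min_area = 1,
                      frame_interval = cfg$frame_interval)
  expect_equal(nrow(got), nrow(truth))
  expect_true(all(abs(got$max_area_um2 - truth$area_um2) /
                    truth$area_um2 < 0.05))
  expect_true(all(abs(got$translocation_um - truth$translocation_um) < 0.06))
})
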