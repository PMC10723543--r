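test_that("simulator parameter validation names the offending field", {
  expect_error(wave_sim_params(recruit_prob = 1.5), "recruit_prob")
  expect_error(wave_sim_params(strength_alpha = -1), "strength_alpha")
  expect_error(wave_sim_params(calcium_decay_per_frame = 1), "calcium_decay")
  expect_error(wave_sim_params(n_frames = 0), "n_frames")
})

test_that("zero initiation rate and zero noise give an all-zero movie", {
  m <- simulate_waves(wave_sim_params(height = 8, width = 8, n_frames = 40,
                                      strength_alpha = 0, noise_sd = 0))
  expect_true(all(m$frames == 0))
})

test_that("simulation is bitwise deterministic given seed and parameters", {
  p <- wave_sim_params(height = 10, width = 12, n_frames = 60, seed = 5)
  expect_identical(simulate_waves(p)$frames, simulate_waves(p)$frames)
  p2 <- p; p2$seed <- 6L
  expect_false(identical(simulate_waves(p)$frames, simulate_waves(p2)$frames))
})

test_that("movie intensities stay in [0, 1] and movies carry metadata", {
  m <- simulate_waves(wave_sim_params(height = 8, width = 8, n_frames = 80,
                                      noise_sd = 0.3, seed = 2))
  expect_gte(min(m$frames), 0)
  expect_lte(max(m$frames), 1)
  expect_identical(m$source_tag, "simulated")
  expect_identical(m$seed, 2L)
})

test_that("event frequency is nondecreasing in wave strength", {
  count_events <- function(alpha, seed) {
    p <- wave_sim_params(height = 12, width = 12, n_frames = 150,
                         strength_alpha = alpha, noise_sd = 0, seed = seed)
    nrow(extract_events(simulate_waves(p), 0.2, 2))
  }
  seeds <- 1:20
  lo <- mean(vapply(seeds, function(s) count_events(0.05, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) count_events(0.5, s), numeric(1)))
  expect_gte(hi, lo)
})

test_that("event extraction follows the maximal-run rule", {
  m <- movie_from_activity(c(0, 1, 1, 1, 0, 1, 0))
  ev <- extract_events(m, 0.5, 2)
  expect_equal(ev$start_frame, 1L)
  expect_equal(ev$end_frame, 4L)

  expect_equal(nrow(extract_events(movie_from_activity(rep(0, 6)), 0.5, 1)), 0)

  ev_all <- extract_events(movie_from_activity(rep(1, 6)), 0.5, 1)
  expect_equal(as.integer(unlist(ev_all)), c(0L, 6L))
})

test_that("extracted events are maximal, disjoint and sorted on real output", {
  fx <- tiny_wave_fixture()
  ev <- fx$events
  expect_true(nrow(ev) >= 2)
  expect_true(all(diff(ev$start_frame) > 0))
  expect_true(all(ev$end_frame > ev$start_frame))
  if (nrow(ev) > 1)
    expect_true(all(ev$start_frame[-1] >= ev$end_frame[-nrow(ev)]))
  active <- apply(fx$movie$frames, 1, max) > 0.2
  TT <- length(active)
  for (i in seq_len(nrow(ev))) {
    s <- ev$start_frame[i]; e <- ev$end_frame[i]
    expect_true(all(active[(s + 1):e]))
    if (s > 0) expect_false(active[s])        # frame before start inactive
    if (e < TT) expect_false(active[e + 1])   # frame at end inactive
  }
})

test_that("spatial shuffle preserves each frame's pixel multiset", {
  fx <- tiny_wave_fixture()
  sh <- shuffle_movie(fx$movie, fx$events, "spatial", seed = 3)
  for (t in c(1, 5, 50)) {
    expect_equal(sort(as.vector(sh$movie$frames[t, , ])),
                 sort(as.vector(fx$movie$frames[t, , ])))
  }
  expect_false(identical(sh$movie$frames, fx$movie$frames))
  expect_identical(as.data.frame(sh$events), as.data.frame(fx$events))
})

test_that("temporal shuffle permutes whole frames and keeps event ranges", {
  fx <- tiny_wave_fixture()
  sh <- shuffle_movie(fx$movie, fx$events, "temporal", seed = 3)
  key <- function(fr) apply(fr, 1, function(x) paste(signif(x, 10),
                                                     collapse = ","))
  expect_setequal(key(sh$movie$frames), key(fx$movie$frames))
  expect_identical(as.data.frame(sh$events), as.data.frame(fx$events))
})

test_that("kind none is the identity and shuffles are seed-deterministic", {
  fx <- tiny_wave_fixture()
  expect_identical(shuffle_movie(fx$movie, fx$events, "none")$movie$frames,
                   fx$movie$frames)
  a <- shuffle_movie(fx$movie, fx$events, "spatial", seed = 11)
  b <- shuffle_movie(fx$movie, fx$events, "spatial", seed = 11)
  expect_identical(a$movie$frames, b$movie$frames)
})

test_that("spatiotemporal shuffle composes the two single shuffles", {
  fx <- tiny_wave_fixture()
  st <- shuffle_movie(fx$movie, fx$events, "spatiotemporal", seed = 9)
  tm <- shuffle_movie(fx$movie, fx$events, "temporal", seed = 9)
  sp <- shuffle_movie(tm$movie, tm$events, "spatial", seed = 10)
  expect_identical(st$movie$frames, sp$movie$frames)
  expect_match(st$movie$source_tag, "shuffled-spatiotemporal")
})

test_that("movie archives round-trip exactly with metadata", {
  fr <- array(runif(5 * 8 * 8), c(5, 8, 8))
  m <- wave_movie(fr, frame_rate_hz = 12.5, source_tag = "simulated",
                  seed = 4L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_movie(m, path)
  m2 <- load_movie(path)
  expect_identical(m2$frames, fr)
  expect_identical(m2$frame_rate_hz, 12.5)
  expect_identical(m2$source_tag, "simulated")
  expect_identical(m2$seed, 4L)
})

test_that("TIFF round trip is exact on the 16-bit grid", {
  fx <- tiny_wave_fixture()
  m <- quantize_movie(fx$movie)
  path <- withr::local_tempfile(fileext = ".tif")
  save_movie(m, path)
  m2 <- load_movie(path)
  expect_equal(m2$frames, m$frames, tolerance = 1e-12)
  expect_equal(m2$frame_rate_hz, m$frame_rate_hz)
})

test_that("corrupt or non-grayscale input is rejected with a clear error", {
  expect_error(load_movie(file.path(tempdir(), "nope.tif")), "not found")
  # 3-channel stack
  path <- withr::local_tempfile(fileext = ".tif")
  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  tiff::writeTIFF(rgb, path)
  jsonlite::write_json(list(frame_rate_hz = 10, source_tag = "real"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_movie(path), "channels")
  # archive with out-of-range intensities
  path2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(array(2, c(2, 3, 3)), path2)
  jsonlite::write_json(list(frame_rate_hz = 10, source_tag = "real"),
                       paste0(path2, ".json"), auto_unbox = TRUE)
  expect_error(load_movie(path2), "\\[0, 1\\]")
})

test_that("event tables validate and round-trip as CSV", {
  expect_error(wave_events(c(0, 2), c(3, 4)), "disjoint")
  expect_error(wave_events(0, 0), "exceed")
  ev <- wave_events(c(4, 0), c(6, 2))   # sorted on construction
  expect_equal(ev$start_frame, c(0L, 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  save_events(ev, path)
  expect_identical(as.data.frame(load_events(path)), as.data.frame(ev))
})
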