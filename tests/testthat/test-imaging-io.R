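test_that("movies round-trip through multi-page TIFF", {
  cfg <- quick_config(n_rois = 3, duration_s = 3)
  sim <- simulate_traces(cfg)
  rm_ <- render_movie(sim, field_px = 32, seed = 41)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie(rm_$movie, path)
  back <- read_movie(path, frame_rate_hz = cfg$frame_rate_hz)
  expect_length(back$functional, length(rm_$movie$functional))
  expect_equal(back$functional[[5]], rm_$movie$functional[[5]],
               tolerance = 1e-6)
  expect_equal(back$anatomical[[30]], rm_$movie$anatomical[[30]],
               tolerance = 1e-6)
})

test_that("channel-layout violations raise format errors", {
  path <- withr::local_tempfile(fileext = ".tif")
  pages <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  tiff::writeTIFF(pages, path)
  expect_error(read_movie(path), "even page count")
  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages[1:2], p2)
  expect_error(read_movie(NULL, channel_layout = c(path, p2)),
               "disagree on frame count")
  expect_error(two_channel_movie(pages[1:2], pages[1:2], frame_rate_hz = 0))
})

test_that("trace extraction averages mask pixels per frame", {
  frames <- lapply(1:4, function(t) matrix(7, 8, 8))
  mv <- two_channel_movie(frames, frames, 10)
  labels <- matrix(0L, 8, 8); labels[2:3, 2:3] <- 1L; labels[6, 6] <- 2L
  rois <- roi_set_from_labels(labels)
  tr <- extract_traces(mv, rois)
  expect_true(all(tr$traces == 7))
  # a 1-pixel mask reproduces that pixel's time series
  frames2 <- lapply(1:4, function(t) {
    m <- matrix(0, 8, 8); m[6, 6] <- t * 1.5; m
  })
  mv2 <- two_channel_movie(frames2, frames2, 10)
  tr2 <- extract_traces(mv2, rois)
  expect_equal(unname(tr2$traces[, "roi2"]), (1:4) * 1.5)
  # out-of-bounds mask names the ROI
  badrois <- roi_set(list(bad = cbind(9, 2)))
  expect_error(extract_traces(mv, badrois), "bad")
})

test_that("extraction is linear in the movie", {
  set.seed(7)
  f1 <- lapply(1:3, function(t) matrix(rnorm(64), 8, 8))
  f2 <- lapply(1:3, function(t) matrix(rnorm(64), 8, 8))
  mix <- Map(function(a, b) 2 * a + 3 * b, f1, f2)
  labels <- matrix(0L, 8, 8); labels[3:5, 3:5] <- 1L
  rois <- roi_set_from_labels(labels)
  t_mix <- extract_traces(two_channel_movie(mix, mix, 10), rois)$traces
  t1 <- extract_traces(two_channel_movie(f1, f1, 10), rois)$traces
  t2 <- extract_traces(two_channel_movie(f2, f2, 10), rois)$traces
  expect_equal(t_mix, 2 * t1 + 3 * t2)
})

test_that("polygon ROIs fill with the even-odd rule", {
  sq <- rbind(c(2.5, 2.5), c(2.5, 5.5), c(5.5, 5.5), c(5.5, 2.5))
  rs <- roi_set_from_polygons(list(sq), dim = c(10, 10))
  m <- rs$roi_masks[[1]]
  expect_setequal(paste(m[, 1], m[, 2]),
                  paste(rep(3:5, each = 3), rep(3:5, times = 3)))
})

test_that("neuropil annuli exclude every ROI in the set", {
  labels <- matrix(0L, 40, 40)
  labels[10:13, 10:13] <- 1L
  labels[10:13, 16:19] <- 2L   # adjacent neighbour
  labels[30:32, 30:32] <- 3L
  rois <- roi_set_from_labels(labels)
  rois <- derive_neuropil_masks(rois, dim = c(40, 40),
                                annulus_inner_px = 1, annulus_outer_px = 6)
  all_roi <- do.call(rbind, rois$roi_masks)
  for (k in seq_along(rois$neuropil_masks)) {
    np <- rois$neuropil_masks[[k]]
    expect_gt(nrow(np), 0)
    # brute-force set intersection with the union of all ROI pixels
    expect_length(intersect(paste(np[, 1], np[, 2]),
                            paste(all_roi[, 1], all_roi[, 2])), 0)
  }
  expect_error(derive_neuropil_masks(rois, c(40, 40), 5, 5), "exceed")
})

test_that("neuropil correction is identity at r = 0 and for constant neuropil", {
  set.seed(9)
  tr <- matrix(rnorm(200, 100), 100, 2)
  np <- matrix(rnorm(200, 70), 100, 2)
  expect_equal(neuropil_correct(tr, np, r = 0), tr, ignore_attr = TRUE)
  np_const <- matrix(50, 100, 2)
  expect_equal(neuropil_correct(tr, np_const, r = 0.7), tr,
               ignore_attr = TRUE)
  expect_error(neuropil_correct(tr, np, r = 1), "\\[0, 1\\)")
})

test_that("correction with the true ratio removes neuropil contamination", {
  set.seed(10)
  clean <- 100 + as.numeric(stats::filter(rnorm(2000), rep(1, 5) / 5,
                                          sides = 2))
  clean[is.na(clean)] <- 100
  np <- 70 + cumsum(rnorm(2000, 0, 0.5))
  mixed <- clean + 0.7 * (np - median(np))
  corrected <- neuropil_correct(cbind(mixed), cbind(np), r = 0.7)
  expect_lt(abs(cor(corrected[, 1], np)), abs(cor(mixed, np)))
  expect_equal(corrected[, 1], clean, ignore_attr = TRUE)
})

test_that("registration recovers applied shifts and is shift-consistent", {
  cfg <- quick_config(n_rois = 6, duration_s = 8)
  sim <- simulate_traces(cfg)
  set.seed(12)
  sh <- cbind(sample(-3:3, 80, TRUE), sample(-3:3, 80, TRUE))
  sh[1, ] <- 0
  rm_ <- render_movie(sim, field_px = 48, shifts = sh, noise_sd = 0.5,
                      seed = 43)
  reg <- register_frames(rm_$movie, reference = 0)
  expect_equal(unname(round(reg$shifts)), sh)
  # identical frames give zero shifts
  still <- render_movie(sim, field_px = 48, shifts = NULL, noise_sd = 0,
                        seed = 44)
  reg0 <- register_frames(still$movie)
  expect_true(all(round(reg0$shifts) == 0))
  # constant anatomy: degenerate registration warns, returns zeros
  flat <- lapply(1:4, function(i) matrix(1, 16, 16))
  expect_warning(rf <- register_frames(two_channel_movie(flat, flat, 10)),
                 "degenerate")
  expect_true(all(rf$shifts == 0))
})
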