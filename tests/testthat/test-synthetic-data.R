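test_that("invalid simulation parameters are rejected", {
  expect_error(sim_config(whisking_mean_bout_s = 0), "bout and gap")
  expect_error(sim_config(tau_rise_s = 2, tau_decay_s = 1.5), "tau_decay")
  expect_error(sim_config(neuropil_ratio = 1), "neuropil_ratio")
  expect_error(sim_config(shared_drive_weight = -0.1), "shared_drive_weight")
  expect_error(sim_config(frame_rate_hz = 0), "frame_rate_hz")
})

test_that("simulation is deterministic given (config, seed)", {
  cfg <- quick_config()
  b1 <- simulate_behavior(cfg)
  b2 <- simulate_behavior(cfg)
  expect_identical(b1, b2)
  s1 <- simulate_traces(cfg)
  s2 <- simulate_traces(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_traces(cfg, seed = 999)
  expect_false(identical(s1$traces, s2$traces) &&
                 identical(s1$traces, s3$traces))
})

test_that("stationary whisking fraction matches the renewal closed form", {
  # bout 2 s / gap 6 s alternating renewal: stationary fraction 2/8 = 0.25
  cfg <- sim_config(n_rois = 1, duration_s = 1000, whisking_mean_bout_s = 2,
                    whisking_mean_gap_s = 6, seed = 5)
  fr <- vapply(1:8, function(k) {
    mean(simulate_behavior(cfg, seed = k)$state)
  }, numeric(1))
  # ~125 bouts per run x 8 runs; SE of the pooled fraction ~ 0.006
  expect_lt(abs(mean(fr) - 0.25), 0.02)
})

test_that("behavior intensity is elevated during whisking", {
  cfg <- quick_config()
  b <- simulate_behavior(cfg)
  expect_gt(mean(b$intensity[b$state == 1]) - mean(b$intensity[b$state == 0]),
            3 * cfg$behavior_noise_sd)
})

test_that("zero event rates give event-free baseline traces", {
  cfg <- quick_config(event_rate_stationary_hz = 0,
                      event_rate_whisking_hz = 0, responsive_fraction = 1)
  sim <- simulate_traces(cfg)
  expect_true(all(lengths(sim$ground_truth$event_frames) == 0))
  # clean traces are exactly the flat baseline
  expect_true(all(sim$clean == cfg$baseline_f))
})

test_that("a noiseless single event peaks at its amplitude", {
  cfg <- sim_config(n_rois = 1, duration_s = 120, noise_sd = 0,
                    drift_amplitude = 0, neuropil_ratio = 0,
                    event_rate_stationary_hz = 0.005,
                    event_rate_whisking_hz = 0.005, amplitude_mean = 1,
                    amplitude_sd = 0, responsive_fraction = 0, seed = 1)
  sim <- simulate_traces(cfg)
  ev <- sim$ground_truth$event_frames[[1]]
  expect_length(ev, 1)
  # kernel is peak-normalized, so the excursion above baseline equals
  # amplitude x baseline_f
  expect_equal(max(sim$traces[, 1]) - cfg$baseline_f, 1 * cfg$baseline_f,
               tolerance = 1e-10)
})

test_that("total event count obeys the Poisson counting oracle", {
  # rate 0.05 Hz, 600 s, 50 ROIs -> lambda = 1500
  cfg <- sim_config(n_rois = 50, duration_s = 600,
                    event_rate_stationary_hz = 0.05,
                    event_rate_whisking_hz = 0.05, responsive_fraction = 0,
                    shared_drive_weight = 0, seed = 11)
  sim <- simulate_traces(cfg)
  total <- sum(lengths(sim$ground_truth$event_frames))
  lambda <- 0.05 * 600 * 50
  ci <- qpois(c(0.005, 0.995), lambda)
  expect_gte(total, ci[1])
  expect_lte(total, ci[2])
})

test_that("shared drive preserves per-ROI marginal event rates", {
  n_roi <- 40
  base <- list(n_rois = n_roi, duration_s = 600, responsive_fraction = 1,
               event_rate_whisking_hz = 0.25)
  cfg0 <- do.call(sim_config, c(base, list(shared_drive_weight = 0, seed = 21)))
  cfgw <- do.call(sim_config, c(base, list(shared_drive_weight = 0.5, seed = 21)))
  n0 <- sum(lengths(simulate_traces(cfg0)$ground_truth$event_frames))
  nw <- sum(lengths(simulate_traces(cfgw)$ground_truth$event_frames))
  # identical expected totals; allow 3 SD of the Poisson difference
  expect_lt(abs(n0 - nw), 3 * sqrt(n0 + nw))
})

test_that("shared drive creates whisking-state coincidence", {
  cfg <- sim_config(n_rois = 20, duration_s = 600, responsive_fraction = 1,
                    shared_drive_weight = 0.6, seed = 23)
  sim <- simulate_traces(cfg)
  gt <- sim$ground_truth
  # count frames where >= 3 ROIs fire together
  tab <- table(unlist(gt$event_frames))
  expect_gt(sum(tab >= 3), 5)
})

test_that("rendered movies honor applied shifts and static anatomy", {
  cfg <- quick_config(n_rois = 3, duration_s = 5)
  sim <- simulate_traces(cfg)
  rm0 <- render_movie(sim, field_px = 48, shifts = NULL, noise_sd = 0.5,
                      seed = 31)
  # zero shifts: anatomical frames equal up to noise
  d <- rm0$movie$anatomical[[1]] - rm0$movie$anatomical[[25]]
  expect_lt(sd(d), 1.5 * sqrt(2) * 0.5)
  expect_equal(rm0$applied_shifts, matrix(0, 50, 2))

  sh <- matrix(0, 50, 2); sh[10, ] <- c(3, -2)
  rmS <- render_movie(sim, field_px = 48, shifts = sh, noise_sd = 0.2,
                      seed = 32)
  est <- estimate_shift(rmS$movie$anatomical[[10]],
                        rmS$movie$anatomical[[1]])
  expect_equal(round(unname(est)), c(3, -2))
})

test_that("ROI placement fails cleanly when the field is too crowded", {
  cfg <- quick_config(n_rois = 200, duration_s = 2)
  sim <- simulate_traces(cfg)
  expect_error(render_movie(sim, field_px = 32, min_separation_px = 8),
               "could not place")
})
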