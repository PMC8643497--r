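test_that("transient detection applies the 3xSD / 10-frame rule", {
  z <- manual_dff(rep(0, 500), noise_sd = 0.01)
  expect_identical(nrow(detect_transients(z)), 0L)

  # 9-frame pulse at 5xSD: below the duration minimum
  x <- rep(0, 500); x[100:108] <- 0.05
  expect_identical(nrow(detect_transients(manual_dff(x, 0.01))), 0L)

  # two 12-frame pulses with a sub-threshold gap: exactly two events
  x <- rep(0, 500); x[100:111] <- 0.05; x[130:141] <- 0.08
  ev <- detect_transients(manual_dff(x, 0.01), roi_id = "r")
  expect_identical(nrow(ev), 2L)
  oracle <- oracle_runs(x, 3 * 0.01, 10)
  expect_equal(ev$onset, oracle[, 1])
  expect_equal(ev$peak_dff, c(0.05, 0.08))
  expect_true(all(ev$onset <= ev$peak_frame & ev$peak_frame < ev$offset))
})

test_that("detection equals the run-length oracle on random traces", {
  set.seed(25)
  for (rep in 1:10) {
    x <- as.numeric(stats::filter(rnorm(800, 0, 0.02), rep(1, 3) / 3,
                                  sides = 2))
    x[is.na(x)] <- 0
    x <- x + 0.1 * (runif(800) < 0.01)
    d <- manual_dff(x, 0.01)
    ev <- detect_transients(d, threshold_sd = 2, min_duration_frames = 4)
    oracle <- oracle_runs(x, 2 * 0.01, 4)
    expect_identical(nrow(ev), if (is.null(oracle)) 0L else nrow(oracle))
    if (nrow(ev)) expect_equal(ev$onset, oracle[, 1])
  }
})

test_that("raising thresholds never increases the event count", {
  set.seed(26)
  x <- abs(as.numeric(stats::filter(rnorm(2000, 0, 0.03), rep(1, 8) / 8,
                                    sides = 2)))
  x[is.na(x)] <- 0
  d <- manual_dff(x, 0.01)
  counts_thr <- vapply(c(1, 2, 3, 4), function(th) {
    nrow(detect_transients(d, threshold_sd = th, min_duration_frames = 5))
  }, numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
  counts_len <- vapply(c(3, 6, 10, 15), function(ml) {
    nrow(detect_transients(d, threshold_sd = 2, min_duration_frames = ml))
  }, numeric(1))
  expect_true(all(diff(counts_len) <= 0))
})

test_that("whisking epochs are detected, merged, and filtered", {
  expect_identical(nrow(detect_whisking_epochs(rep(3, 400))$epochs), 0L)

  cfg <- sim_config(n_rois = 1, duration_s = 600, seed = 6)
  b <- simulate_behavior(cfg)
  ep <- detect_whisking_epochs(b$intensity)
  gt <- b$state == 1
  iou <- sum(gt & ep$mask) / sum(gt | ep$mask)
  expect_gte(iou, 0.9)
  expect_true(all(diff(ep$epochs$onset) > 0))
  expect_true(all(ep$epochs$offset > ep$epochs$onset))

  # two bouts separated by 2 frames merge under merge_gap_frames = 5
  set.seed(27)
  beh <- rnorm(300, 10, 0.3)
  beh[100:120] <- beh[100:120] + 20
  beh[123:143] <- beh[123:143] + 20
  ep2 <- detect_whisking_epochs(beh, merge_gap_frames = 5)
  expect_true(any(ep2$epochs$onset <= 100 & ep2$epochs$offset >= 143))
  ep3 <- detect_whisking_epochs(beh, merge_gap_frames = 1)
  in_bump <- ep3$epochs$onset >= 95 & ep3$epochs$offset <= 148
  expect_identical(sum(in_bump), 2L)

  expect_warning(detect_whisking_epochs(rnorm(30, 10), window_frames = 50),
                 "global")
})

test_that("transient state labels follow the association window", {
  ev <- data.frame(roi_id = "r", onset = c(5L, 40L, 90L),
                   offset = c(20L, 55L, 105L), peak_frame = c(10L, 45L, 95L),
                   peak_dff = 1, state = "unlabeled",
                   stringsAsFactors = FALSE)
  none <- epochs_from_state(rep(0, 200))
  expect_true(all(label_transient_states(ev, none)$state == "spontaneous"))

  # epoch [50, 60): window [50 - 10, 60 + 20) = [40, 80)
  st <- rep(0, 200); st[51:60] <- 1
  ep <- epochs_from_state(st)
  lab <- label_transient_states(ev, ep)
  expect_equal(lab$state, c("spontaneous", "whisking", "spontaneous"))
  # onset exactly 1 s before epoch start is included (closed lower bound)
  ev2 <- ev[1, ]; ev2$onset <- 40L
  expect_equal(label_transient_states(ev2, ep)$state, "whisking")
  ev2$onset <- 39L
  expect_equal(label_transient_states(ev2, ep)$state, "spontaneous")
})

test_that("random labels equal the interval-membership oracle", {
  set.seed(28)
  for (rep in 1:5) {
    st <- rep(0, 1000)
    for (k in 1:6) {
      a <- sample(900, 1); st[a:(a + sample(30, 1))] <- 1
    }
    st <- st[1:1000]
    ep <- epochs_from_state(st)
    ons <- sort(sample(0:990, 25))
    ev <- data.frame(roi_id = "r", onset = ons, offset = ons + 5L,
                     peak_frame = ons, peak_dff = 1, state = "unlabeled",
                     stringsAsFactors = FALSE)
    lab <- label_transient_states(ev, ep)
    want <- vapply(ons, function(f) {
      any(ep$epochs$onset - 10 <= f & f < ep$epochs$offset + 20)
    }, logical(1))
    expect_equal(lab$state == "whisking", want)
  }
})

test_that("activity summaries partition events and encode the angle", {
  st <- rep(0, 6000); st[1001:2000] <- 1
  ep <- epochs_from_state(st)
  wmask <- whisking_associated_mask(ep)
  ev <- data.frame(roi_id = "r", onset = c(500L, 1100L, 3000L),
                   offset = c(515L, 1115L, 3015L),
                   peak_frame = c(505L, 1105L, 3005L),
                   peak_dff = c(0.3, 0.6, 0.4), state = "unlabeled",
                   stringsAsFactors = FALSE)
  ev <- label_transient_states(ev, ep)
  s <- summarize_activity(ev, ep)
  expect_identical(s$n_events, 3L)
  # every event labeled exactly once; state durations partition the recording
  expect_identical(sum(ev$state == "whisking") + sum(ev$state == "spontaneous"),
                   3L)
  expect_identical(sum(wmask) + sum(!wmask), 6000L)
  # frequencies: 1 whisking event / whisking-associated min, 2 / remaining
  expect_equal(s$freq_whisking, 1 / (sum(wmask) / 10 / 60))
  expect_equal(s$freq_stationary, 2 / (sum(!wmask) / 10 / 60))
  expect_equal(s$amp_whisking, 0.6)
  expect_equal(s$amp_stationary, 0.35)
  # total frequency lies between the state-specific frequencies
  ftot <- 3 / (6000 / 10 / 60)
  expect_gte(ftot, min(s$freq_stationary, s$freq_whisking))
  expect_lte(ftot, max(s$freq_stationary, s$freq_whisking))

  # angle limits: only spontaneous -> 0 deg; only whisking -> 90; equal -> 45
  ev_s <- ev[ev$state == "spontaneous", ]
  expect_equal(summarize_activity(ev_s, ep)$angle_deg, 0)
  ev_w <- ev[ev$state == "whisking", ]
  expect_equal(summarize_activity(ev_w, ep)$angle_deg, 90)
  st2 <- rep(0, 6000); st2[2001:3950] <- 1  # margins make 50/50 time split
  ep2 <- epochs_from_state(st2)
  m2 <- whisking_associated_mask(ep2)
  ev_eq <- data.frame(roi_id = "r", onset = c(100L, 2500L),
                      offset = c(115L, 2515L), peak_frame = c(105L, 2505L),
                      peak_dff = 0.5, state = "unlabeled",
                      stringsAsFactors = FALSE)
  ev_eq <- label_transient_states(ev_eq, ep2)
  s2 <- summarize_activity(ev_eq, ep2)
  expect_equal(s2$angle_deg, atan2(1 / sum(m2), 1 / sum(!m2)) * 180 / pi)
})

test_that("whisking-responsiveness classification behaves at both extremes", {
  st <- rep(0, 2000)
  for (on in seq(100, 1900, by = 100)) st[on:(on + 20)] <- 1
  ep <- epochs_from_state(st[1:2000])
  flat <- manual_dff(rep(0, 2000), 0.01)
  r0 <- classify_whisking_responsive(flat, ep)
  expect_false(isTRUE(r0$responsive))

  # deterministic responder: a transient right after every onset
  kern <- calcium_kernel(0.05, 1.5, 10)
  x <- rep(0, 2000)
  for (on in ep$epochs$onset) {
    idx <- (on + 3):min(2000, on + 2 + length(kern))
    x[idx] <- x[idx] + 0.5 * kern[seq_along(idx)]
  }
  set.seed(29)
  d <- manual_dff(x + rnorm(2000, 0, 0.01), 0.01)
  r1 <- classify_whisking_responsive(d, ep)
  expect_true(r1$responsive)
  expect_gt(r1$mean_onset_response, 0.1)
  # aligned matrix rows are baseline-subtracted onset segments
  expect_identical(nrow(r1$aligned), r1$n_onsets)
  expect_lt(max(abs(rowMeans(r1$aligned[, 1:5]))), 0.05)

  # too few onsets leaves the ROI unclassified
  ep1 <- epochs_from_state(c(rep(0, 500), rep(1, 20), rep(0, 1480)))
  expect_true(is.na(classify_whisking_responsive(d, ep1)$responsive))
})
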