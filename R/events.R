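#' Detect calcium transients in a ΔF/F trace
#'
#' Maximal runs of frames whose ΔF/F exceeds `threshold_sd` times the
#' noise-band SD and that last at least `min_duration_frames` (1 s at 10 Hz)
#' become transient events; an ROI with at least one event is classified
#' active.
#'
#' @param dff a `dff_trace` from [compute_dff()].
#' @param threshold_sd threshold as a multiple of the noise-band SD
#'   (default 3).
#' @param min_duration_frames minimum run length in frames (default 10).
#' @param roi_id identifier attached to the events.
#' @return data.frame of events: `roi_id`, `onset` / `offset` (0-based,
#'   half-open), `peak_frame`, `peak_dff`, `state` (initialized
#'   `"unlabeled"`; see [label_transient_states()]). Zero rows when silent.
#' @export
detect_transients <- function(dff, threshold_sd = 3,
                              min_duration_frames = 10,
                              roi_id = "roi1") {
  stopifnot(inherits(dff, "dff_trace"))
  x <- dff$dff
  if (!dff$usable) {
    return(empty_events())
  }
  if (dff$noise_sd == 0) {
    if (stats::sd(x) > 0) {
      stop("noise_sd is 0 on a nonconstant trace; run the trace through the processing pipeline first")
    }
    return(empty_events())
  }
  thr <- threshold_sd * dff$noise_sd
  runs <- runs_from_mask(x > thr)
  if (nrow(runs) == 0) return(empty_events())
  runs <- runs[runs$offset - runs$onset >= min_duration_frames, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_events())
  peaks <- t(vapply(seq_len(nrow(runs)), function(k) {
    idx <- (runs$onset[k] + 1L):runs$offset[k]
    j <- idx[which.max(x[idx])]
    c(j - 1L, x[j])
  }, numeric(2)))
  data.frame(roi_id = roi_id, onset = runs$onset, offset = runs$offset,
             peak_frame = as.integer(peaks[, 1]), peak_dff = peaks[, 2],
             state = "unlabeled", stringsAsFactors = FALSE)
}

#' @keywords internal
empty_events <- function() {
  data.frame(roi_id = character(0), onset = integer(0), offset = integer(0),
             peak_frame = integer(0), peak_dff = numeric(0),
             state = character(0), stringsAsFactors = FALSE)
}

#' Detect transients for every ROI of a processed set
#' @param dff_set named list of `dff_trace` objects ([process_traces()]).
#' @inheritParams detect_transients
#' @return combined event data.frame.
#' @export
detect_transients_set <- function(dff_set, threshold_sd = 3,
                                  min_duration_frames = 10) {
  out <- lapply(names(dff_set), function(id) {
    detect_transients(dff_set[[id]], threshold_sd, min_duration_frames, id)
  })
  do.call(rbind, out)
}

#' Detect whisking epochs from a behavior-video intensity trace
#'
#' The whisker-ROI mean intensity trace is corrected for slow fluctuations
#' by subtracting the 8th percentile of a 50-frame sliding window; frames
#' whose corrected intensity exceeds `threshold_sd` times the noise-band SD
#' (noise band estimated as for fluorescence traces) are classified as
#' whisking. Epochs separated by fewer than `merge_gap_frames` are merged,
#' and epochs shorter than `min_epoch_frames` dropped.
#'
#' @param behavior numeric intensity trace sampled at the imaging rate.
#' @param frame_rate_hz sampling rate.
#' @param window_frames detrend window (default 50).
#' @param threshold_sd threshold multiple of the noise-band SD (default 3).
#' @param merge_gap_frames merge epochs separated by fewer frames
#'   (default 5, i.e. 0.5 s).
#' @param min_epoch_frames drop epochs shorter than this (default 3).
#' @param detrend_percentile sliding-window percentile (default 8).
#' @return object of class `whisking_epochs`: list with `epochs`
#'   (data.frame of 0-based half-open intervals), `mask` (per-frame
#'   logical), `noise_sd`, `params`.
#' @export
detect_whisking_epochs <- function(behavior, frame_rate_hz = 10,
                                   window_frames = 50, threshold_sd = 3,
                                   merge_gap_frames = 5,
                                   min_epoch_frames = 3,
                                   detrend_percentile = 8) {
  n <- length(behavior)
  if (n < window_frames) {
    warning("trace shorter than the detrend window; using the global percentile")
  }
  det <- behavior - sliding_percentile(behavior, window_frames,
                                       detrend_percentile)
  # the sliding-percentile residual sits above zero even at rest; center it
  # on the quiet-frame baseline (the F0 analog) before thresholding, exactly
  # as the fluorescence path does through delta-F/F
  est <- estimate_f0_and_noise(det, frame_rate_hz)
  active <- if (est$noise_sd > 0)
              det - est$f0 > threshold_sd * est$noise_sd
            else rep(FALSE, n)
  ep <- runs_from_mask(active)
  # merge epochs separated by short gaps
  if (nrow(ep) > 1 && merge_gap_frames > 0) {
    keep <- ep[1, , drop = FALSE]
    for (k in 2:nrow(ep)) {
      if (ep$onset[k] - keep$offset[nrow(keep)] < merge_gap_frames) {
        keep$offset[nrow(keep)] <- ep$offset[k]
      } else {
        keep <- rbind(keep, ep[k, ])
      }
    }
    ep <- keep
  }
  ep <- ep[ep$offset - ep$onset >= min_epoch_frames, , drop = FALSE]
  rownames(ep) <- NULL
  structure(list(
    epochs = ep,
    mask = mask_from_intervals(ep$onset, ep$offset, n),
    noise_sd = est$noise_sd,
    n_frames = n,
    frame_rate_hz = frame_rate_hz,
    params = list(window_frames = window_frames, threshold_sd = threshold_sd,
                  merge_gap_frames = merge_gap_frames,
                  min_epoch_frames = min_epoch_frames)
  ), class = "whisking_epochs")
}

#' Construct whisking epochs directly from a known state sequence
#'
#' Used with synthetic ground truth, or when epochs come from an external
#' detector.
#'
#' @param state per-frame 0/1 (or logical) whisking indicator.
#' @param frame_rate_hz sampling rate.
#' @return a `whisking_epochs` object.
#' @export
epochs_from_state <- function(state, frame_rate_hz = 10) {
  mask <- as.logical(state)
  ep <- runs_from_mask(mask)
  structure(list(epochs = ep, mask = mask, noise_sd = NA_real_,
                 n_frames = length(mask), frame_rate_hz = frame_rate_hz,
                 params = list(source = "state_sequence")),
            class = "whisking_epochs")
}

#' Per-frame whisking-associated mask including pre/post margins
#'
#' Whisking-associated time runs from `pre_s` before each epoch onset to
#' `post_s` after its offset — the same window used to label transients —
#' so state-specific event frequencies use matching numerators and
#' denominators.
#'
#' @param epochs a `whisking_epochs` object.
#' @param pre_s margin before onset (default 1 s).
#' @param post_s margin after offset (default 2 s).
#' @return logical per-frame mask.
#' @export
whisking_associated_mask <- function(epochs, pre_s = 1, post_s = 2) {
  fps <- epochs$frame_rate_hz
  mask_from_intervals(epochs$epochs$onset - seconds_to_frames(pre_s, fps),
                      epochs$epochs$offset + seconds_to_frames(post_s, fps),
                      epochs$n_frames)
}

#' Label transients as whisking-associated or spontaneous
#'
#' An event is whisking-associated iff its onset frame falls within
#' `[epoch_onset - pre_s, epoch_offset + post_s)` of any whisking epoch
#' (default 1 s before onset to 2 s after offset); all other events are
#' spontaneous. Events are assigned by onset only; an event straddling a
#' boundary is not split.
#'
#' @param events event data.frame from [detect_transients_set()].
#' @param epochs a `whisking_epochs` object.
#' @param pre_s,post_s association margins in seconds.
#' @return the events with `state` filled in.
#' @export
label_transient_states <- function(events, epochs, pre_s = 1, post_s = 2) {
  mask <- whisking_associated_mask(epochs, pre_s, post_s)
  if (nrow(events)) {
    inside <- mask[events$onset + 1L]
    events$state <- ifelse(inside, "whisking", "spontaneous")
  }
  events
}

#' Summarize per-ROI activity by behavioral state
#'
#' State-specific transient frequencies (events/min) and mean peak
#' amplitudes, plus the activity angle `atan2(freq_whisking,
#' freq_stationary)` in degrees: 0 deg marks activity exclusively during
#' stationary epochs, 90 deg exclusively whisking-associated activity.
#' Whisking-associated time includes the 1 s pre / 2 s post margins,
#' mirroring the event-labeling rule.
#'
#' @param events labeled event data.frame ([label_transient_states()]).
#' @param epochs a `whisking_epochs` object.
#' @param roi_ids ROIs to summarize (default: those present in `events`).
#' @param pre_s,post_s association margins in seconds.
#' @return data.frame, one row per ROI: `roi_id`, `n_events`,
#'   `freq_stationary`, `freq_whisking` (events/min), `amp_stationary`,
#'   `amp_whisking` (mean peak ΔF/F, NA when no events in that state),
#'   `is_active`, `angle_deg` (NA for inactive ROIs).
#' @export
summarize_activity <- function(events, epochs, roi_ids = NULL,
                               pre_s = 1, post_s = 2) {
  if (is.null(roi_ids)) roi_ids <- unique(events$roi_id)
  mask <- whisking_associated_mask(epochs, pre_s, post_s)
  fps <- epochs$frame_rate_hz
  t_whisk_min <- sum(mask) / fps / 60
  t_stat_min <- sum(!mask) / fps / 60
  rows <- lapply(roi_ids, function(id) {
    ev <- events[events$roi_id == id, , drop = FALSE]
    n_w <- sum(ev$state == "whisking")
    n_s <- sum(ev$state == "spontaneous")
    fw <- if (t_whisk_min > 0) n_w / t_whisk_min else NA_real_
    fs <- if (t_stat_min > 0) n_s / t_stat_min else NA_real_
    angle <- if (nrow(ev) > 0 && is.finite(fw) && is.finite(fs) &&
                 (fw + fs) > 0) {
      atan2(fw, fs) * 180 / pi
    } else NA_real_
    data.frame(
      roi_id = id, n_events = nrow(ev),
      freq_stationary = fs, freq_whisking = fw,
      amp_stationary = if (n_s) mean(ev$peak_dff[ev$state == "spontaneous"])
                       else NA_real_,
      amp_whisking = if (n_w) mean(ev$peak_dff[ev$state == "whisking"])
                     else NA_real_,
      is_active = nrow(ev) > 0,
      angle_deg = angle,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Classify an ROI as whisking-responsive
#'
#' For each whisking onset, the response is the mean ΔF/F over
#' `(onset + 0.5 s, onset + 1.5 s]` and the baseline the mean over
#' `[onset - 0.5 s, onset)`. A one-sided paired test across onsets
#' (Wilcoxon signed-rank by default, optionally paired t-test) at level
#' `alpha` decides responsiveness. Onsets within 2 s of the recording start
#' or with an incomplete response window are excluded. The returned
#' onset-aligned matrix holds each onset's ΔF/F segment normalized by
#' subtracting its own pre-onset baseline mean (the heat-map convention).
#'
#' @param dff a `dff_trace`.
#' @param epochs a `whisking_epochs` object.
#' @param response_window numeric `c(from_s, to_s)` after onset
#'   (default 0.5–1.5 s).
#' @param baseline_s pre-onset baseline length (default 0.5 s).
#' @param alpha test level (default 0.05).
#' @param min_onsets minimum usable onsets (default 5); fewer leaves the
#'   ROI unclassified (`responsive = NA`).
#' @param test `"wilcoxon"` or `"ttest"`.
#' @param segment_pre_s,segment_post_s extent of the returned aligned
#'   segments around onset.
#' @return list with `responsive` (TRUE/FALSE/NA), `p_value`, `n_onsets`,
#'   `mean_onset_response` (mean response minus baseline across onsets),
#'   `aligned` (onsets x frames matrix of baseline-subtracted segments),
#'   `aligned_time_s` (time axis of the segment columns).
#' @export
classify_whisking_responsive <- function(dff, epochs,
                                         response_window = c(0.5, 1.5),
                                         baseline_s = 0.5, alpha = 0.05,
                                         min_onsets = 5,
                                         test = c("wilcoxon", "ttest"),
                                         segment_pre_s = 0.5,
                                         segment_post_s = 2) {
  test <- match.arg(test)
  stopifnot(inherits(dff, "dff_trace"))
  fps <- dff$frame_rate_hz
  x <- dff$dff
  n <- length(x)
  onsets <- epochs$epochs$onset
  min_start <- seconds_to_frames(2, fps)
  resp_lo <- seconds_to_frames(response_window[1], fps)
  resp_hi <- seconds_to_frames(response_window[2], fps)
  base_w <- seconds_to_frames(baseline_s, fps)
  seg_pre <- seconds_to_frames(segment_pre_s, fps)
  seg_post <- seconds_to_frames(segment_post_s, fps)

  baseline <- numeric(0); response <- numeric(0)
  segs <- list()
  for (on in onsets) {
    if (on < min_start) next
    if (on + resp_hi >= n || on + seg_post >= n) next
    b_idx <- (on - base_w):(on - 1L) + 1L        # [onset - 0.5 s, onset)
    r_idx <- (on + resp_lo + 1L):(on + resp_hi) + 1L # (onset+0.5, onset+1.5]
    b <- mean(x[b_idx]); r <- mean(x[r_idx])
    baseline <- c(baseline, b); response <- c(response, r)
    s_idx <- (on - seg_pre):(on + seg_post) + 1L
    segs[[length(segs) + 1L]] <- x[s_idx] - b
  }
  n_on <- length(baseline)
  aligned <- if (n_on) do.call(rbind, segs) else
    matrix(numeric(0), 0, seg_pre + seg_post + 1L)
  time_s <- seq(-seg_pre, seg_post) / fps
  if (n_on < min_onsets) {
    return(list(responsive = NA, p_value = NA_real_, n_onsets = n_on,
                mean_onset_response = if (n_on) mean(response - baseline)
                                      else NA_real_,
                aligned = aligned, aligned_time_s = time_s))
  }
  d <- response - baseline
  p <- if (all(d == 0)) {
    1
  } else if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(response, baseline, paired = TRUE,
                                        alternative = "greater",
                                        exact = FALSE)$p.value)
  } else {
    stats::t.test(response, baseline, paired = TRUE,
                  alternative = "greater")$p.value
  }
  list(responsive = is.finite(p) && p < alpha, p_value = p, n_onsets = n_on,
       mean_onset_response = mean(d), aligned = aligned,
       aligned_time_s = time_s)
}

#' Responsiveness classification for a full ROI set
#'
#' @param dff_set named list of `dff_trace` objects.
#' @inheritParams classify_whisking_responsive
#' @return data.frame with one row per ROI: `roi_id`, `responsive`,
#'   `p_value`, `n_onsets`, `mean_onset_response`.
#' @export
classify_whisking_responsive_set <- function(dff_set, epochs,
                                             response_window = c(0.5, 1.5),
                                             baseline_s = 0.5, alpha = 0.05,
                                             min_onsets = 5,
                                             test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  rows <- lapply(names(dff_set), function(id) {
    r <- classify_whisking_responsive(dff_set[[id]], epochs, response_window,
                                      baseline_s, alpha, min_onsets, test)
    data.frame(roi_id = id, responsive = r$responsive, p_value = r$p_value,
               n_onsets = r$n_onsets,
               mean_onset_response = r$mean_onset_response,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
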