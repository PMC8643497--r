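#' Select isolated transients
#'
#' Keeps an event iff it is not followed by a subsequent transient of the
#' same ROI within `isolation_s` (onset-to-onset, default 10 s). The rule is
#' strictly forward-looking: a preceding event does not disqualify —
#' baseline integrity before the onset is enforced separately in
#' [compute_kinetics()].
#'
#' @param events event data.frame (any state labels).
#' @param frame_rate_hz sampling rate.
#' @param isolation_s isolation window in seconds.
#' @return subset of `events`.
#' @export
select_isolated_transients <- function(events, frame_rate_hz = 10,
                                       isolation_s = 10) {
  if (nrow(events) == 0) return(events)
  win <- isolation_s * frame_rate_hz
  keep <- logical(nrow(events))
  for (id in unique(events$roi_id)) {
    idx <- which(events$roi_id == id)
    ons <- events$onset[idx]
    for (k in seq_along(idx)) {
      later <- ons[ons > ons[k] & ons <= ons[k] + win]
      keep[idx[k]] <- length(later) == 0
    }
  }
  events[keep, , drop = FALSE]
}

#' Detect transient onsets from the first derivative
#'
#' The ΔF/F trace is smoothed with a 7-frame moving average; its first
#' derivative (central differences) is thresholded at `threshold_sd` times
#' the derivative's baseline SD, computed over frames outside all detected
#' transients. The first frame of each maximal supra-threshold run is an
#' onset.
#'
#' @param dff a `dff_trace`.
#' @param events detected transients for this ROI, used to define
#'   event-free baseline frames.
#' @param smooth_frames moving-average width (default 7).
#' @param threshold_sd threshold multiple of the baseline derivative SD
#'   (default 3.5).
#' @return integer vector of 0-based onset frames.
#' @export
detect_onsets_by_derivative <- function(dff, events, smooth_frames = 7,
                                        threshold_sd = 3.5) {
  stopifnot(inherits(dff, "dff_trace"))
  x <- moving_average(dff$dff, smooth_frames)
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[1] <- x[2] - x[1]; d[n] <- x[n] - x[n - 1]

  in_event <- mask_from_intervals(events$onset, events$offset, n)
  baseline_frames <- which(!in_event)
  if (length(baseline_frames) < 10) {
    stop("no event-free frames to estimate the derivative baseline; review detection thresholds")
  }
  sd_base <- stats::sd(d[baseline_frames])
  if (sd_base == 0) return(integer(0))
  runs <- runs_from_mask(d > threshold_sd * sd_base)
  runs$onset
}

#' Average isolated transients and quantify their kinetics
#'
#' Segments aligned at each isolated onset are baseline-subtracted by their
#' own mean over the 1 s preceding the onset, then averaged into a mean
#' transient. The peak amplitude is its maximum; the decay time is the time
#' after the peak at which the mean transient first drops to 36.8% of the
#' peak, and the half-decay time the analogous 50% crossing, both located
#' by linear interpolation between frames (a frame is 100 ms at 10 Hz, too
#' coarse otherwise). Onsets whose pre-onset second overlaps a previous
#' event, or whose post-window leaves the recording, are dropped.
#'
#' @param dff a `dff_trace`.
#' @param onsets 0-based isolated onset frames.
#' @param events full event table for the ROI (for pre-window integrity).
#' @param pre_s baseline window before onset (default 1 s).
#' @param post_s segment length after onset (default 8 s).
#' @return list with `n_isolated`, `peak_amplitude`, `decay_time_s`,
#'   `half_decay_s` (NA when the mean transient never crosses the
#'   threshold), `mean_transient`, `time_s`. `NULL` if no usable onset.
#' @export
compute_kinetics <- function(dff, onsets, events = empty_events(),
                             pre_s = 1, post_s = 8) {
  stopifnot(inherits(dff, "dff_trace"))
  fps <- dff$frame_rate_hz
  x <- dff$dff
  n <- length(x)
  pre_f <- seconds_to_frames(pre_s, fps)
  post_f <- seconds_to_frames(post_s, fps)
  segs <- list()
  for (on in onsets) {
    if (on - pre_f < 0 || on + post_f >= n) next
    pre_idx <- (on - pre_f):(on - 1L)
    # drop segments whose baseline window overlaps an earlier event
    if (nrow(events)) {
      overlap <- any(events$offset > min(pre_idx) & events$onset <= max(pre_idx))
      if (overlap) next
    }
    seg <- x[(on - pre_f):(on + post_f) + 1L]
    segs[[length(segs) + 1L]] <- seg - mean(x[pre_idx + 1L])
  }
  if (!length(segs)) return(NULL)
  m <- colMeans(do.call(rbind, segs))
  time_s <- seq(-pre_f, post_f) / fps
  post_peak_start <- pre_f + 1L # search the peak from onset on
  rel <- m[post_peak_start:length(m)]
  pk <- which.max(rel)
  peak <- rel[pk]
  decay_time <- crossing_time(rel, pk, 0.368 * peak) / fps
  half_decay <- crossing_time(rel, pk, 0.5 * peak) / fps
  list(n_isolated = length(segs), peak_amplitude = peak,
       decay_time_s = decay_time, half_decay_s = half_decay,
       mean_transient = m, time_s = time_s)
}

# first crossing of `level` after index `from` in vector v, in frames
# (linear interpolation between samples); NA if never crossed
#' @keywords internal
crossing_time <- function(v, from, level) {
  for (i in from:(length(v) - 1L)) {
    if (v[i] > level && v[i + 1L] <= level) {
      frac <- (v[i] - level) / (v[i] - v[i + 1L])
      return((i - from) + frac)
    }
  }
  NA_real_
}

#' Per-ROI kinetics summary for a processed set
#'
#' Runs derivative-based onset detection, forward isolation, and kinetics
#' averaging per ROI.
#'
#' @param dff_set named list of `dff_trace` objects.
#' @param events combined event table ([detect_transients_set()]).
#' @param frame_rate_hz sampling rate.
#' @param isolation_s isolation window (default 10 s).
#' @param smooth_frames,threshold_sd onset-detector parameters.
#' @param pre_s,post_s averaging window around onset.
#' @return data.frame, one row per ROI with >= 1 usable isolated transient:
#'   `roi_id`, `n_isolated`, `peak_amplitude`, `decay_time_s`,
#'   `half_decay_s`.
#' @export
summarize_kinetics <- function(dff_set, events, frame_rate_hz = 10,
                               isolation_s = 10, smooth_frames = 7,
                               threshold_sd = 3.5, pre_s = 1, post_s = 8) {
  rows <- list()
  for (id in names(dff_set)) {
    ev <- events[events$roi_id == id, , drop = FALSE]
    ons <- tryCatch(
      detect_onsets_by_derivative(dff_set[[id]], ev, smooth_frames,
                                  threshold_sd),
      error = function(e) integer(0))
    if (!length(ons)) next
    ev_d <- data.frame(roi_id = id, onset = ons,
                       offset = ons + 1L, peak_frame = ons,
                       peak_dff = NA_real_, state = "unlabeled",
                       stringsAsFactors = FALSE)
    iso <- select_isolated_transients(ev_d, frame_rate_hz, isolation_s)
    if (!nrow(iso)) next
    k <- compute_kinetics(dff_set[[id]], iso$onset, ev, pre_s, post_s)
    if (is.null(k)) next
    rows[[length(rows) + 1L]] <- data.frame(
      roi_id = id, n_isolated = k$n_isolated,
      peak_amplitude = k$peak_amplitude,
      decay_time_s = k$decay_time_s, half_decay_s = k$half_decay_s,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(roi_id = character(0), n_isolated = integer(0),
                      peak_amplitude = numeric(0), decay_time_s = numeric(0),
                      half_decay_s = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
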