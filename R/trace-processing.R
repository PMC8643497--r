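#' Low-pass filter a fluorescence trace
#'
#' Zero-phase smoothing with unit DC gain. For cutoffs strictly below the
#' Nyquist frequency a second-order Butterworth filter is applied forward
#' and backward (`signal::filtfilt`). At the Nyquist frequency itself — the
#' case of a 5 Hz cutoff on a 10 Hz recording, where a sharp filter would be
#' the identity — a 3-frame binomial kernel (1, 2, 1)/4 is used instead: it
#' has unit DC gain, zero gain at Nyquist, and no phase shift. The choice is
#' recorded in the `method` attribute.
#'
#' @param x numeric trace.
#' @param cutoff_hz cutoff frequency; must satisfy 0 < cutoff <= Nyquist.
#' @param frame_rate_hz sampling rate.
#' @return filtered trace with attribute `method`.
#' @export
lowpass_filter <- function(x, cutoff_hz = 5, frame_rate_hz = 10) {
  nyq <- frame_rate_hz / 2
  if (cutoff_hz <= 0 || cutoff_hz > nyq) {
    stop("cutoff_hz must lie in (0, Nyquist = ", nyq, "]")
  }
  if (cutoff_hz >= nyq * (1 - 1e-9)) {
    n <- length(x)
    if (n < 3L) return(x)
    core <- (x[1:(n - 2)] + 2 * x[2:(n - 1)] + x[3:n]) / 4
    out <- c((3 * x[1] + x[2]) / 4, core, (x[n - 1] + 3 * x[n]) / 4)
    attr(out, "method") <- "binomial3"
    return(out)
  }
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  out <- as.numeric(signal::filtfilt(bf, x))
  attr(out, "method") <- "butterworth2"
  out
}

#' Remove slow baseline fluctuations by sliding-percentile subtraction
#'
#' Subtracts the 8th percentile of a centered 1000-frame sliding window
#' (defaults), truncated at the trace edges. With `keep_baseline = TRUE`
#' the median of the removed trend is added back, so the slow fluctuations
#' are flattened while the absolute baseline level — which F0 estimation
#' and the ΔF/F denominator rely on — is preserved.
#'
#' @param x numeric trace.
#' @param window_frames sliding window length (default 1000).
#' @param percentile window percentile subtracted (default 8).
#' @param keep_baseline add back the median of the estimated trend.
#' @return detrended trace.
#' @export
detrend <- function(x, window_frames = 1000, percentile = 8,
                    keep_baseline = FALSE) {
  if (window_frames < 3) stop("window_frames must be >= 3")
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie in (0, 100)")
  }
  if (window_frames > length(x)) {
    warning("window longer than trace; subtracting the global percentile")
  }
  trend <- sliding_percentile(x, window_frames, percentile)
  out <- x - trend
  if (keep_baseline) out <- out + stats::median(trend)
  out
}

#' Estimate F0 and the noise-band SD of a trace
#'
#' The noise band is the residual after subtracting the 8th percentile of a
#' 1-second centered sliding window. F0 is the median of the trace over
#' frames whose noise-band value lies at or below the noise band's 70th
#' percentile (frames dominated by transients are thereby excluded);
#' `noise_sd` is the SD of the noise band over those same frames, the scale
#' used by every downstream multiple-of-noise-SD threshold.
#'
#' @param x detrended trace (fluorescence units).
#' @param frame_rate_hz sampling rate; the percentile window is 1 s.
#' @param percentile window percentile (default 8).
#' @param band_percentile cutoff percentile of the noise band (default 70).
#' @return list with `f0`, `noise_sd` (fluorescence units), `noise_band`
#'   (full-length residual trace).
#' @export
estimate_f0_and_noise <- function(x, frame_rate_hz = 10, percentile = 8,
                                  band_percentile = 70) {
  w <- max(3L, seconds_to_frames(1, frame_rate_hz))
  band <- x - sliding_percentile(x, w, percentile)
  cut <- stats::quantile(band, band_percentile / 100, names = FALSE, type = 7)
  quiet <- band <= cut
  f0 <- stats::median(x[quiet])
  noise_sd <- stats::sd(band[quiet])
  if (is.na(noise_sd)) noise_sd <- 0
  list(f0 = f0, noise_sd = noise_sd, noise_band = band)
}

#' Full raw-trace to ΔF/F pipeline for one ROI
#'
#' Processing order: low-pass filter (5 Hz) -> baseline-preserving
#' sliding-percentile detrend (8th percentile, 1000 frames) -> F0 and
#' noise-band estimation on the detrended trace -> ΔF/F = (F - F0) / F0.
#' `noise_sd` is returned in ΔF/F units (the fluorescence-unit noise SD
#' divided by F0) so detection thresholds apply directly to the ΔF/F trace.
#' Neuropil correction, when wanted, is applied beforehand via
#' [neuropil_correct()].
#'
#' @param x raw (neuropil-corrected) fluorescence trace.
#' @param frame_rate_hz sampling rate.
#' @param lowpass_hz low-pass cutoff (default 5).
#' @param detrend_window_frames sliding detrend window (default 1000).
#' @param detrend_percentile detrend percentile (default 8).
#' @param f0_band_percentile noise-band cutoff percentile (default 70).
#' @return object of class `dff_trace`: list with `dff`, `f0`, `noise_sd`
#'   (ΔF/F units), `frame_rate_hz`, `usable` (FALSE when F0 <= 0, in which
#'   case `dff` is NA), and `params`.
#' @export
compute_dff <- function(x, frame_rate_hz = 10, lowpass_hz = 5,
                        detrend_window_frames = 1000,
                        detrend_percentile = 8,
                        f0_band_percentile = 70) {
  lp <- lowpass_filter(x, lowpass_hz, frame_rate_hz)
  lowpass_method <- attr(lp, "method")
  lp <- as.numeric(lp)
  det <- detrend(lp, detrend_window_frames, detrend_percentile,
                 keep_baseline = TRUE)
  est <- estimate_f0_and_noise(det, frame_rate_hz,
                               percentile = detrend_percentile,
                               band_percentile = f0_band_percentile)
  usable <- is.finite(est$f0) && est$f0 > 0
  dff <- if (usable) (det - est$f0) / est$f0 else rep(NA_real_, length(x))
  structure(list(
    dff = dff,
    f0 = est$f0,
    noise_sd = if (usable) est$noise_sd / est$f0 else NA_real_,
    frame_rate_hz = frame_rate_hz,
    usable = usable,
    params = list(lowpass_hz = lowpass_hz,
                  lowpass_method = lowpass_method,
                  detrend_window_frames = detrend_window_frames,
                  detrend_percentile = detrend_percentile,
                  f0_band_percentile = f0_band_percentile)
  ), class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dff_trace: %d frames @ %.3g Hz, F0 = %.3g, noise SD = %.4g dF/F%s\n",
              length(x$dff), x$frame_rate_hz, x$f0, x$noise_sd,
              if (x$usable) "" else " [UNUSABLE: F0 <= 0]"))
  invisible(x)
}

#' Process a matrix of raw traces into a list of ΔF/F traces
#'
#' Applies [neuropil_correct()] (when neuropil traces are given) and
#' [compute_dff()] column-wise. ROIs whose F0 is non-positive are flagged
#' unusable and reported via message.
#'
#' @param traces n_frames x n_rois raw trace matrix.
#' @param neuropil optional matching neuropil matrix.
#' @param neuropil_r contamination coefficient (default 0.7).
#' @inheritParams compute_dff
#' @return named list of `dff_trace` objects.
#' @export
process_traces <- function(traces, neuropil = NULL, neuropil_r = 0.7,
                           frame_rate_hz = 10, lowpass_hz = 5,
                           detrend_window_frames = 1000,
                           detrend_percentile = 8,
                           f0_band_percentile = 70) {
  corrected <- neuropil_correct(traces, neuropil, neuropil_r)
  ids <- colnames(traces)
  if (is.null(ids)) ids <- paste0("roi", seq_len(ncol(traces)))
  out <- lapply(seq_len(ncol(corrected)), function(j) {
    compute_dff(corrected[, j], frame_rate_hz, lowpass_hz,
                detrend_window_frames, detrend_percentile,
                f0_band_percentile)
  })
  names(out) <- ids
  bad <- ids[!vapply(out, `[[`, logical(1), "usable")]
  if (length(bad)) {
    message("excluded (F0 <= 0): ", paste(bad, collapse = ", "))
  }
  out
}
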