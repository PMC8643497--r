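#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from a single user seed. Independent
#' sub-streams (behavior, per-ROI event trains, rendering noise, shuffles)
#' are derived by hashing the master seed with a small stream index, so each
#' component is reproducible in isolation.
#'
#' @param seed master integer seed.
#' @param stream non-negative integer stream index.
#' @return an integer seed < 2^31 suitable for [set.seed()].
#' @keywords internal
derive_seed <- function(seed, stream) {
  # multiplicative hash mod a prime below 2^31; keeps streams well separated
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807 + 12345) %%
               2147483629)
}

#' Convert seconds to a whole number of frames
#' @keywords internal
seconds_to_frames <- function(s, frame_rate_hz) {
  as.integer(round(s * frame_rate_hz))
}

#' Moving-average smoothing with edge truncation
#'
#' Centered moving average over `width` frames; windows are truncated at the
#' trace edges so the DC gain is 1 everywhere (no padding, no fabricated
#' samples).
#'
#' @param x numeric vector.
#' @param width window width in frames (odd widths are symmetric).
#' @return smoothed numeric vector, same length as `x`.
#' @export
moving_average <- function(x, width) {
  stopifnot(is.numeric(x), width >= 1)
  width <- as.integer(width)
  if (width == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half_l <- (width - 1L) %/% 2L
  half_r <- width - 1L - half_l
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Sliding percentile baseline
#'
#' Percentile of a centered sliding window, truncated at the edges (early and
#' late frames use shorter windows). Percentiles use linear interpolation
#' between order statistics (`stats::quantile` type 7), fixed because low
#' percentiles on short windows are sensitive to the convention.
#'
#' @param x numeric vector.
#' @param window window length in frames.
#' @param p percentile in (0, 100).
#' @return numeric vector of window percentiles, same length as `x`.
#' @export
sliding_percentile <- function(x, window, p) {
  stopifnot(is.numeric(x), window >= 1, p > 0, p < 100)
  n <- length(x)
  window <- as.integer(window)
  if (window >= n) {
    return(rep(stats::quantile(x, p / 100, names = FALSE, type = 7), n))
  }
  .sliding_quantile_cpp(as.numeric(x), window, p / 100)
}

#' Frame-index run detection
#'
#' Maximal runs of TRUE in a logical vector, returned as 0-based half-open
#' [onset, offset) frame intervals — the package-wide interval convention
#' (frame 0 is the first frame; time(frame) = frame / frame_rate_hz).
#'
#' @param mask logical vector.
#' @return data.frame with columns `onset`, `offset` (0-based, half-open).
#' @keywords internal
runs_from_mask <- function(mask) {
  stopifnot(is.logical(mask))
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset = starts[keep] - 1L, offset = ends[keep])
}

#' Build a logical frame mask from 0-based half-open intervals
#' @keywords internal
mask_from_intervals <- function(onsets, offsets, n_frames) {
  m <- logical(n_frames)
  if (length(onsets)) {
    for (k in seq_along(onsets)) {
      lo <- max(0L, onsets[k])
      hi <- min(n_frames, offsets[k])
      if (hi > lo) m[(lo + 1L):hi] <- TRUE
    }
  }
  m
}
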