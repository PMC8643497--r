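#' Estimate the rigid shift between two frames by cross-correlation
#'
#' FFT-based circular cross-correlation; the correlation peak gives the
#' integer displacement of `frame` relative to `reference`, optionally
#' refined to sub-pixel precision by a separable three-point quadratic fit
#' around the peak. Both frames are mean-subtracted first.
#'
#' @param frame,reference numeric matrices of equal size.
#' @param upsample logical; fit the correlation peak quadratically for a
#'   sub-pixel estimate.
#' @return numeric `c(dy, dx)`: the displacement of `frame` relative to
#'   `reference` (positive dy = content moved down). Translating `frame` by
#'   the negated shift aligns it to `reference`.
#' @export
estimate_shift <- function(frame, reference, upsample = TRUE) {
  stopifnot(identical(dim(frame), dim(reference)))
  nr <- nrow(frame); nc <- ncol(frame)
  a <- reference - mean(reference)
  b <- frame - mean(frame)
  if (all(a == 0) || all(b == 0)) return(c(dy = 0, dx = 0))
  # circular cross-correlation cc[m] = sum_x b[x] * a[x - m]: if the frame's
  # content is the reference displaced by s, the peak sits at m = s
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  peak <- which.max(cc)
  pr <- (peak - 1L) %% nr
  pc <- (peak - 1L) %/% nr
  if (upsample) {
    at <- function(r, c) cc[1L + (r %% nr), 1L + (c %% nc)]
    c0 <- at(pr, pc)
    cm <- at(pr - 1L, pc); cp <- at(pr + 1L, pc)
    denom <- cm - 2 * c0 + cp
    off_r <- if (denom != 0) 0.5 * (cm - cp) / denom else 0
    cm <- at(pr, pc - 1L); cp <- at(pr, pc + 1L)
    denom <- cm - 2 * c0 + cp
    off_c <- if (denom != 0) 0.5 * (cm - cp) / denom else 0
    off_r <- max(min(off_r, 0.5), -0.5)
    off_c <- max(min(off_c, 0.5), -0.5)
  } else {
    off_r <- 0; off_c <- 0
  }
  sdy <- (if (pr > nr / 2) pr - nr else pr) + off_r
  sdx <- (if (pc > nc / 2) pc - nc else pc) + off_c
  c(dy = sdy, dx = sdx)
}

#' Rigidly register a two-channel movie on its anatomical channel
#'
#' Per-frame translation is estimated by cross-correlating each anatomical
#' frame against a reference (the mean anatomical frame by default, or a
#' chosen frame); the correcting shift is then applied identically to both
#' channels. Only pure translation is modelled (slight brain displacement);
#' border pixels vacated by shifting are filled with the frame median.
#'
#' @param movie a [two_channel_movie()].
#' @param reference `"mean"` or a 0-based frame index to use as reference.
#' @param subpixel estimate shifts with sub-pixel precision. Applied shifts
#'   are rounded to integers unless `apply_subpixel = TRUE` (integer
#'   application is exactly invertible and introduces no interpolation).
#' @param apply_subpixel apply fractional shifts by bilinear interpolation.
#' @return list with `movie` (registered) and `shifts` (n_frames x 2 matrix
#'   of estimated (dy, dx) displacements of each frame relative to the
#'   reference; the negated shift was applied to correct).
#' @export
register_frames <- function(movie, reference = "mean", subpixel = TRUE,
                            apply_subpixel = FALSE) {
  stopifnot(inherits(movie, "two_channel_movie"))
  n <- length(movie$anatomical)
  ref <- if (identical(reference, "mean")) {
    Reduce(`+`, movie$anatomical) / n
  } else {
    movie$anatomical[[as.integer(reference) + 1L]]
  }
  if (stats::sd(ref) == 0) {
    warning("anatomical reference is constant; registration is degenerate, returning zero shifts")
    return(list(movie = movie,
                shifts = matrix(0, n, 2,
                                dimnames = list(NULL, c("dy", "dx")))))
  }
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  fun <- vector("list", n)
  ana <- vector("list", n)
  for (t in seq_len(n)) {
    sh <- estimate_shift(movie$anatomical[[t]], ref, upsample = subpixel)
    shifts[t, ] <- sh
    appl <- if (apply_subpixel) -sh else -round(sh)
    fun[[t]] <- translate_frame(movie$functional[[t]], appl[1], appl[2])
    ana[[t]] <- translate_frame(movie$anatomical[[t]], appl[1], appl[2])
  }
  list(movie = two_channel_movie(fun, ana, movie$frame_rate_hz,
                                 movie$pixel_size_um),
       shifts = shifts)
}
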