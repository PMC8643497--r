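#' Two-channel movie container
#'
#' A functional (calcium indicator) channel and an anatomical (static red
#' fluorophore) channel with matching geometry, plus acquisition metadata.
#'
#' @param functional,anatomical lists of equally sized numeric matrices
#'   (one per frame).
#' @param frame_rate_hz acquisition rate in Hz.
#' @param pixel_size_um optional pixel size in micrometres.
#' @return object of class `two_channel_movie`.
#' @export
two_channel_movie <- function(functional, anatomical, frame_rate_hz,
                              pixel_size_um = NA_real_) {
  stopifnot(length(functional) == length(anatomical),
            length(functional) >= 1, frame_rate_hz > 0)
  dims <- dim(functional[[1]])
  ok <- vapply(c(functional, anatomical),
               function(f) identical(dim(f), dims), logical(1))
  if (!all(ok)) stop("all frames must share the same dimensions")
  structure(list(functional = functional, anatomical = anatomical,
                 frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um),
            class = "two_channel_movie")
}

#' @export
print.two_channel_movie <- function(x, ...) {
  d <- dim(x$functional[[1]])
  cat(sprintf("two_channel_movie: %d frames, %d x %d px, %.3g Hz\n",
              length(x$functional), d[1], d[2], x$frame_rate_hz))
  invisible(x)
}

# fixed intensity scale used when serializing to [0,1] float TIFF
.TIFF_SCALE <- 65535

#' Write a two-channel movie as multi-page TIFF
#'
#' Channels are interleaved (page 1 functional frame 1, page 2 anatomical
#' frame 1, ...) in a single 32-bit float file, intensities divided by a
#' fixed scale of 65535; [read_movie()] restores the original values.
#'
#' @param movie a [two_channel_movie()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "two_channel_movie"))
  pages <- vector("list", 2L * length(movie$functional))
  pages[seq(1, length(pages), by = 2)] <-
    lapply(movie$functional, function(f) f / .TIFF_SCALE)
  pages[seq(2, length(pages), by = 2)] <-
    lapply(movie$anatomical, function(f) f / .TIFF_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a two-channel movie from multi-page TIFF
#'
#' @param path TIFF written by [write_movie()], or any multi-page TIFF whose
#'   channel interleaving matches `channel_layout`.
#' @param frame_rate_hz acquisition rate to attach (metadata, default 10).
#' @param channel_layout `"interleaved"` (functional page first) or a
#'   two-element character vector of paths `c(functional=, anatomical=)` for
#'   per-channel files.
#' @param pixel_size_um optional pixel size metadata.
#' @return a [two_channel_movie()].
#' @export
read_movie <- function(path, frame_rate_hz = 10,
                       channel_layout = "interleaved",
                       pixel_size_um = NA_real_) {
  read_pages <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1] # drop extra samples
      m * .TIFF_SCALE
    })
  }
  if (identical(channel_layout, "interleaved")) {
    pages <- read_pages(path)
    if (length(pages) %% 2L != 0L) {
      stop(sprintf("interleaved layout needs an even page count; got %d (odd page %d has no partner)",
                   length(pages), length(pages)))
    }
    fun <- pages[seq(1, length(pages), by = 2)]
    ana <- pages[seq(2, length(pages), by = 2)]
  } else if (length(channel_layout) == 2L) {
    fun <- read_pages(channel_layout[[1]])
    ana <- read_pages(channel_layout[[2]])
    if (length(fun) != length(ana)) {
      stop(sprintf("channel files disagree on frame count (%d vs %d)",
                   length(fun), length(ana)))
    }
  } else {
    stop("channel_layout must be \"interleaved\" or two file paths")
  }
  two_channel_movie(fun, ana, frame_rate_hz, pixel_size_um)
}

#' Render a synthetic two-channel movie from simulated traces
#'
#' ROIs are drawn as 2-D Gaussian spots at random non-overlapping centroids.
#' The functional channel follows each ROI's clean trace; the anatomical
#' channel is the static spot pattern plus noise. Optional per-frame rigid
#' shifts (recorded in the ground truth) are applied identically to both
#' channels, emulating brain displacement for registration testing.
#'
#' @param sim output of [simulate_traces()].
#' @param field_px field of view side length in pixels.
#' @param spot_sigma_px Gaussian spot SD in pixels.
#' @param min_separation_px minimum centroid separation.
#' @param shifts `NULL` for a motion-free movie, `"random"` for a smoothed
#'   random integer walk (max +/-3 px), or an n_frames x 2 matrix of
#'   (dy, dx) shifts (may be fractional; applied by bilinear interpolation).
#' @param noise_sd imaging noise SD added per pixel per frame.
#' @param seed seed for placement, motion and pixel noise.
#' @return list with `movie` (a [two_channel_movie()]), `centroids`
#'   (n_rois x 2, row/col), `applied_shifts` (n_frames x 2, dy/dx), `labels`
#'   (integer label matrix: 0 background, k = pixels of ROI k).
#' @export
render_movie <- function(sim, field_px = 64, spot_sigma_px = 2,
                         min_separation_px = 8, shifts = NULL,
                         noise_sd = 1, seed = sim$ground_truth$config$seed) {
  traces <- sim$clean
  n <- nrow(traces)
  n_rois <- ncol(traces)
  cfg <- sim$ground_truth$config
  set.seed(derive_seed(seed, 4L))

  margin <- ceiling(3 * spot_sigma_px) + 4L
  centroids <- matrix(NA_real_, n_rois, 2)
  tries <- 0L
  placed <- 0L
  while (placed < n_rois) {
    cand <- stats::runif(2, margin, field_px - margin)
    ok <- placed == 0L ||
      min(sqrt(rowSums((centroids[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 2, byrow = TRUE))^2))) >=
      min_separation_px
    if (ok) {
      placed <- placed + 1L
      centroids[placed, ] <- cand
    }
    tries <- tries + 1L
    if (tries > 2000L * n_rois) {
      stop("could not place ROIs without overlap; reduce n_rois or min_separation_px")
    }
  }

  yy <- matrix(seq_len(field_px), field_px, field_px)
  xx <- t(yy)
  spots <- vector("list", n_rois)
  labels <- matrix(0L, field_px, field_px)
  for (k in seq_len(n_rois)) {
    d2 <- (yy - centroids[k, 1])^2 + (xx - centroids[k, 2])^2
    spots[[k]] <- exp(-d2 / (2 * spot_sigma_px^2))
    labels[d2 <= (1.5 * spot_sigma_px)^2] <- k
  }
  anatomy_base <- Reduce(`+`, lapply(spots, function(s) s * 0.6 * cfg$baseline_f)) +
    0.1 * cfg$baseline_f

  if (is.null(shifts)) {
    shift_mat <- matrix(0, n, 2)
  } else if (identical(shifts, "random")) {
    raw <- matrix(cumsum(stats::rnorm(2 * n, 0, 0.6)), n, 2)
    raw[, 1] <- raw[, 1] - mean(raw[, 1]); raw[, 2] <- raw[, 2] - mean(raw[, 2])
    shift_mat <- round(pmin(pmax(raw, -3), 3))
    # motion is recoverable only relative to the reference; start at zero
    shift_mat <- sweep(shift_mat, 2, shift_mat[1, ])
    shift_mat <- pmin(pmax(shift_mat, -3), 3)
  } else {
    shift_mat <- as.matrix(shifts)
    stopifnot(nrow(shift_mat) == n, ncol(shift_mat) == 2)
  }

  fun_frames <- vector("list", n)
  ana_frames <- vector("list", n)
  for (t in seq_len(n)) {
    fframe <- matrix(0.05 * cfg$baseline_f, field_px, field_px)
    for (k in seq_len(n_rois)) {
      fframe <- fframe + spots[[k]] * traces[t, k]
    }
    fframe <- translate_frame(fframe, shift_mat[t, 1], shift_mat[t, 2])
    aframe <- translate_frame(anatomy_base, shift_mat[t, 1], shift_mat[t, 2])
    # photodetector counts are non-negative
    fun_frames[[t]] <- pmax(fframe + matrix(stats::rnorm(field_px^2, 0, noise_sd),
                                            field_px, field_px), 0)
    ana_frames[[t]] <- pmax(aframe + matrix(stats::rnorm(field_px^2, 0, noise_sd),
                                            field_px, field_px), 0)
  }

  list(movie = two_channel_movie(fun_frames, ana_frames, cfg$frame_rate_hz),
       centroids = centroids,
       applied_shifts = shift_mat,
       labels = labels)
}

#' Translate a frame by (dy, dx) pixels
#'
#' Positive dy moves content down, positive dx moves it right. Integer
#' shifts relocate pixels exactly; fractional shifts use bilinear
#' interpolation. Vacated border pixels are filled with the frame median.
#'
#' @param frame numeric matrix.
#' @param dy,dx shift in pixels.
#' @return shifted matrix of the same size.
#' @export
translate_frame <- function(frame, dy, dx) {
  if (dy == 0 && dx == 0) return(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  fill <- stats::median(frame)
  if (dy == round(dy) && dx == round(dx)) {
    dy <- as.integer(dy); dx <- as.integer(dx)
    out <- matrix(fill, nr, nc)
    src_r <- seq_len(nr) - dy
    src_c <- seq_len(nc) - dx
    ok_r <- src_r >= 1L & src_r <= nr
    ok_c <- src_c >= 1L & src_c <= nc
    out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
    return(out)
  }
  # bilinear: sample source at (r - dy, c - dx)
  r0 <- floor(dy); fr <- dy - r0
  c0 <- floor(dx); fc <- dx - c0
  s <- function(ddy, ddx) translate_frame(frame, ddy, ddx)
  (1 - fr) * (1 - fc) * s(r0, c0) + (1 - fr) * fc * s(r0, c0 + 1) +
    fr * (1 - fc) * s(r0 + 1, c0) + fr * fc * s(r0 + 1, c0 + 1)
}
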