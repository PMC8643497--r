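#' ROI set
#'
#' Pixel-coordinate masks of manually outlined somata, with optional
#' matching neuropil annuli. Coordinates are (row, col) matrix indices on
#' the movie's pixel grid.
#'
#' @param roi_masks named list; each element an m x 2 integer matrix of
#'   (row, col) pixel coordinates.
#' @param neuropil_masks optional list parallel to `roi_masks`.
#' @param roi_ids stable identifiers; defaults to names of `roi_masks`.
#' @return object of class `roi_set`.
#' @export
roi_set <- function(roi_masks, neuropil_masks = NULL, roi_ids = NULL) {
  if (is.null(roi_ids)) {
    roi_ids <- names(roi_masks)
    if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_along(roi_masks))
  }
  stopifnot(length(roi_ids) == length(roi_masks))
  empty <- vapply(roi_masks, function(m) is.null(m) || nrow(m) == 0, logical(1))
  if (any(empty)) {
    stop("empty ROI mask(s): ", paste(roi_ids[empty], collapse = ", "))
  }
  structure(list(roi_masks = roi_masks, neuropil_masks = neuropil_masks,
                 roi_ids = roi_ids),
            class = "roi_set")
}

#' Build an ROI set from a labeled mask image
#'
#' @param labels integer matrix: 0 = background, k = pixels of ROI k.
#' @return a [roi_set()].
#' @export
roi_set_from_labels <- function(labels) {
  ks <- sort(unique(labels[labels > 0]))
  masks <- lapply(ks, function(k) which(labels == k, arr.ind = TRUE))
  names(masks) <- paste0("roi", ks)
  roi_set(masks)
}

#' Build an ROI set from polygon outlines
#'
#' Polygons are filled on the pixel grid with the even-odd rule applied to
#' pixel centers.
#'
#' @param polygons list of p x 2 matrices of (row, col) vertices.
#' @param dim c(n_rows, n_cols) of the pixel grid.
#' @return a [roi_set()].
#' @export
roi_set_from_polygons <- function(polygons, dim) {
  masks <- lapply(polygons, function(poly) {
    poly <- as.matrix(poly)
    rr <- seq(max(1, floor(min(poly[, 1]))), min(dim[1], ceiling(max(poly[, 1]))))
    cc <- seq(max(1, floor(min(poly[, 2]))), min(dim[2], ceiling(max(poly[, 2]))))
    grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
    inside <- points_in_polygon(grid[, 1], grid[, 2], poly[, 1], poly[, 2])
    grid[inside, , drop = FALSE]
  })
  names(masks) <- paste0("roi", seq_along(masks))
  roi_set(masks)
}

# even-odd ray-casting test, vectorized over query points
#' @keywords internal
points_in_polygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- logical(length(py))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Derive neuropil annulus masks around each ROI
#'
#' For each ROI, the annulus holds pixels whose Euclidean distance to the
#' nearest ROI pixel lies in (inner, outer], excluding pixels belonging to
#' any ROI in the set (so a neighbour's soma never contaminates the local
#' neuropil estimate). Empty annuli are reported with a warning.
#'
#' @param rois a [roi_set()].
#' @param dim c(n_rows, n_cols) of the pixel grid.
#' @param annulus_inner_px,annulus_outer_px inner (exclusive) and outer
#'   (inclusive) distance bounds in pixels; outer must exceed inner.
#' @return the [roi_set()] with `neuropil_masks` filled in.
#' @export
derive_neuropil_masks <- function(rois, dim, annulus_inner_px = 2,
                                  annulus_outer_px = 8) {
  stopifnot(inherits(rois, "roi_set"))
  if (annulus_outer_px <= annulus_inner_px) {
    stop("annulus_outer_px must exceed annulus_inner_px")
  }
  all_roi <- matrix(FALSE, dim[1], dim[2])
  for (m in rois$roi_masks) all_roi[m] <- TRUE

  np <- lapply(seq_along(rois$roi_masks), function(k) {
    m <- rois$roi_masks[[k]]
    r0 <- max(1, floor(min(m[, 1]) - annulus_outer_px))
    r1 <- min(dim[1], ceiling(max(m[, 1]) + annulus_outer_px))
    c0 <- max(1, floor(min(m[, 2]) - annulus_outer_px))
    c1 <- min(dim[2], ceiling(max(m[, 2]) + annulus_outer_px))
    rr <- r0:r1; cc <- c0:c1
    grid_r <- rep(rr, times = length(cc))
    grid_c <- rep(cc, each = length(rr))
    # min distance from each candidate pixel to the ROI pixels
    d2min <- rep(Inf, length(grid_r))
    for (i in seq_len(nrow(m))) {
      d2 <- (grid_r - m[i, 1])^2 + (grid_c - m[i, 2])^2
      d2min <- pmin(d2min, d2)
    }
    d <- sqrt(d2min)
    sel <- d > annulus_inner_px & d <= annulus_outer_px &
      !all_roi[cbind(grid_r, grid_c)]
    out <- cbind(row = grid_r[sel], col = grid_c[sel])
    if (nrow(out) == 0) {
      warning("empty neuropil annulus for ", rois$roi_ids[k])
    }
    out
  })
  names(np) <- names(rois$roi_masks)
  rois$neuropil_masks <- np
  rois
}

#' Extract mean-fluorescence traces from a movie
#'
#' Per frame, the arithmetic mean of the functional-channel pixels within
#' each ROI mask and (when present) each neuropil annulus.
#'
#' @param movie a [two_channel_movie()].
#' @param rois a [roi_set()].
#' @return list with `traces` (n_frames x n_rois matrix), `neuropil`
#'   (matching matrix or NULL), `frame_rate_hz`.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "two_channel_movie"), inherits(rois, "roi_set"))
  d <- dim(movie$functional[[1]])
  check_bounds <- function(masks) {
    for (k in seq_along(masks)) {
      m <- masks[[k]]
      if (nrow(m) > 0 &&
          (min(m) < 1 || max(m[, 1]) > d[1] || max(m[, 2]) > d[2])) {
        stop("mask out of frame bounds for ", rois$roi_ids[k])
      }
    }
  }
  check_bounds(rois$roi_masks)
  n <- length(movie$functional)
  mean_over <- function(masks) {
    out <- matrix(NA_real_, n, length(masks))
    colnames(out) <- rois$roi_ids
    for (t in seq_len(n)) {
      fr <- movie$functional[[t]]
      for (k in seq_along(masks)) {
        if (nrow(masks[[k]]) > 0) out[t, k] <- mean(fr[masks[[k]]])
      }
    }
    out
  }
  traces <- mean_over(rois$roi_masks)
  neuropil <- NULL
  if (!is.null(rois$neuropil_masks)) {
    check_bounds(rois$neuropil_masks)
    neuropil <- mean_over(rois$neuropil_masks)
  }
  list(traces = traces, neuropil = neuropil,
       frame_rate_hz = movie$frame_rate_hz)
}

#' Correct ROI traces for neuropil contamination
#'
#' `corrected(t) = roi(t) - r * (neuropil(t) - median(neuropil))`. The
#' neuropil trace is median-centered before subtraction, so the correction
#' removes contaminating fluctuations without shifting the baseline that F0
#' estimation divides by downstream.
#'
#' @param traces n_frames x n_rois matrix of ROI traces.
#' @param neuropil matching matrix of neuropil traces.
#' @param r contamination coefficient in [0, 1); default 0.7.
#' @return corrected trace matrix with attribute `neuropil_r`.
#' @export
neuropil_correct <- function(traces, neuropil, r = 0.7) {
  if (r < 0 || r >= 1) stop("neuropil coefficient r must lie in [0, 1)")
  if (r == 0 || is.null(neuropil)) {
    attr(traces, "neuropil_r") <- r
    return(traces)
  }
  stopifnot(identical(dim(traces), dim(neuropil)))
  centered <- sweep(neuropil, 2, apply(neuropil, 2, stats::median))
  out <- traces - r * centered
  attr(out, "neuropil_r") <- r
  out
}
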