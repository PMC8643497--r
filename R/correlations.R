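#' Prepare ΔF/F traces for correlation analysis
#'
#' Each trace is smoothed with a 25-frame moving average, then samples below
#' `gate_sd` times the ROI's noise-band SD are set exactly to 0, leaving a
#' sparse, activity-dominated trace.
#'
#' @param dff_set named list of `dff_trace` objects.
#' @param smooth_frames moving-average width (default 25).
#' @param gate_sd gating threshold in noise-SD multiples (default 2).
#' @return n_frames x n_rois matrix of gated traces.
#' @export
prepare_correlation_traces <- function(dff_set, smooth_frames = 25,
                                       gate_sd = 2) {
  out <- vapply(dff_set, function(d) {
    s <- moving_average(d$dff, smooth_frames)
    s[s < gate_sd * d$noise_sd] <- 0
    s
  }, numeric(length(dff_set[[1]]$dff)))
  colnames(out) <- names(dff_set)
  out
}

#' State-restricted pairwise Pearson correlations
#'
#' Pearson R over the frames selected by `state_mask` for every unordered
#' ROI pair. Pairs where either trace is constant on the state frames have
#' undefined R and are returned as NA (and counted).
#'
#' @param gated n_frames x n_rois matrix from
#'   [prepare_correlation_traces()].
#' @param state_mask logical per-frame mask of the state (for whisking,
#'   include the 1 s pre / 2 s post association margins via
#'   [whisking_associated_mask()]).
#' @param min_frames minimum state duration in frames (default 50); shorter
#'   states are skipped with a warning.
#' @return data.frame with `roi_i`, `roi_j`, `r`; attribute `n_undefined`.
#' @export
pairwise_correlations <- function(gated, state_mask, min_frames = 50) {
  stopifnot(nrow(gated) == length(state_mask))
  if (sum(state_mask) < min_frames) {
    warning("state shorter than ", min_frames, " frames; skipping")
    return(structure(data.frame(roi_i = character(0), roi_j = character(0),
                                r = numeric(0), stringsAsFactors = FALSE),
                     n_undefined = 0L))
  }
  sub <- gated[state_mask, , drop = FALSE]
  ids <- colnames(sub)
  nr <- ncol(sub)
  sds <- apply(sub, 2, stats::sd)
  pairs <- utils::combn(nr, 2)
  r <- rep(NA_real_, ncol(pairs))
  ok <- sds[pairs[1, ]] > 0 & sds[pairs[2, ]] > 0
  if (any(ok)) {
    cm <- suppressWarnings(stats::cor(sub))
    r[ok] <- cm[cbind(pairs[1, ok], pairs[2, ok])]
  }
  structure(data.frame(roi_i = ids[pairs[1, ]], roi_j = ids[pairs[2, ]],
                       r = r, stringsAsFactors = FALSE),
            n_undefined = sum(!ok))
}

#' Circular-shift surrogate null for pairwise correlations
#'
#' Each ROI's full-length gated trace is circularly shifted by an
#' independent uniform offset in `[1, n_frames]` before restriction to the
#' state frames, preserving every trace's autocorrelation and marginal
#' distribution while destroying cross-trace alignment. Shifting the full
#' trace first (rather than the state-restricted fragments) keeps the
#' surrogate's temporal structure intact.
#'
#' @inheritParams pairwise_correlations
#' @param n_shuffles number of shuffle repetitions (default 100).
#' @param seed RNG seed for the shift offsets.
#' @return data.frame with `shuffle`, `roi_i`, `roi_j`, `r` pooling all
#'   repetitions.
#' @export
shuffled_correlations <- function(gated, state_mask, n_shuffles = 100,
                                  seed = 1L, min_frames = 50) {
  stopifnot(n_shuffles >= 1)
  n <- nrow(gated)
  set.seed(derive_seed(seed, 5L))
  out <- vector("list", n_shuffles)
  for (s in seq_len(n_shuffles)) {
    offs <- sample.int(n, ncol(gated), replace = TRUE) # in [1, n]
    shifted <- gated
    for (j in seq_len(ncol(gated))) {
      o <- offs[j] %% n
      if (o > 0) shifted[, j] <- c(gated[(n - o + 1L):n, j],
                                   gated[seq_len(n - o), j])
    }
    pc <- suppressWarnings(pairwise_correlations(shifted, state_mask,
                                                 min_frames))
    if (nrow(pc)) pc$shuffle <- s
    out[[s]] <- pc
  }
  res <- do.call(rbind, out)
  res[, c("shuffle", "roi_i", "roi_j", "r")]
}

#' Compare a metric between two groups
#'
#' Two-sample comparison with the test matched to the metric's
#' distributional character: Kolmogorov–Smirnov for distribution shape,
#' Mann–Whitney (ranksum) for non-normal location, Student's t for normal
#' location.
#'
#' @param a,b numeric metric values for the two groups (>= 3 each).
#' @param test `"ks"`, `"ranksum"`, or `"ttest"`.
#' @param metric_name label carried into the result.
#' @return data.frame row: `metric`, `test`, `statistic`, `p_value`,
#'   `median_a`, `median_b`, `direction` (sign of median(b) - median(a)).
#' @export
compare_groups <- function(a, b, test = c("ks", "ranksum", "ttest"),
                           metric_name = "metric") {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 finite values")
  }
  res <- switch(test,
    ks = suppressWarnings(stats::ks.test(a, b)),
    ranksum = suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)),
    ttest = stats::t.test(a, b)
  )
  data.frame(metric = metric_name, test = test,
             statistic = unname(res$statistic), p_value = res$p.value,
             median_a = stats::median(a), median_b = stats::median(b),
             direction = sign(stats::median(b) - stats::median(a)),
             stringsAsFactors = FALSE)
}
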