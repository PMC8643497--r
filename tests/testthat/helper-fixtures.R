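# shared fixtures, built in code at test time

# small, fast config for unit tests
quick_config <- function(...) {
  args <- utils::modifyList(list(n_rois = 5, duration_s = 120, seed = 101),
                            list(...))
  do.call(sim_config, args)
}

# a dff_trace wrapper around a literal dff vector with a chosen noise SD,
# for detector unit tests that need exact control of the trace
manual_dff <- function(dff, noise_sd, frame_rate_hz = 10) {
  structure(list(dff = dff, f0 = 1, noise_sd = noise_sd,
                 frame_rate_hz = frame_rate_hz, usable = TRUE,
                 params = list()),
            class = "dff_trace")
}

# brute-force reference for maximal supra-threshold runs
oracle_runs <- function(x, thr, min_len) {
  above <- x > thr
  out <- NULL
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) out <- rbind(out, c(i - 1L, j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# event-level matching: a true event frame is recalled when covered by a
# detected episode's [onset - tol, offset + tol); a detected episode is
# correct when it covers at least one true event frame
match_events <- function(true_frames, events, tol = 3) {
  rec <- vapply(true_frames, function(f) {
    any(events$onset - tol <= f & f < events$offset + tol)
  }, logical(1))
  prec <- vapply(seq_len(nrow(events)), function(k) {
    any(true_frames >= events$onset[k] - tol &
        true_frames < events$offset[k] + tol)
  }, logical(1))
  list(recall = mean(rec), precision = mean(prec))
}
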