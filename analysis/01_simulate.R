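#!/usr/bin/env Rscript
# Simulate one control-like field of view with ground truth: behavior video
# intensity, ROI + neuropil fluorescence traces, and a small rendered
# two-channel movie with known rigid motion for the registration step.

suppressPackageStartupMessages(library(calwhisk))

out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_rois = 30, duration_s = 600, seed = 42)
beh <- simulate_behavior(cfg)
sim <- simulate_traces(cfg, behavior = beh)

write.csv(data.frame(frame = seq_along(beh$intensity) - 1L,
                     intensity = beh$intensity, state = beh$state),
          file.path(out_dir, "behavior.csv"), row.names = FALSE)
write.csv(as.data.frame(sim$traces), file.path(out_dir, "traces_raw.csv"),
          row.names = FALSE)
write.csv(as.data.frame(sim$neuropil), file.path(out_dir, "traces_neuropil.csv"),
          row.names = FALSE)
gt_events <- do.call(rbind, lapply(seq_along(sim$ground_truth$event_frames),
  function(k) {
    f <- sim$ground_truth$event_frames[[k]]
    if (!length(f)) return(NULL)
    data.frame(roi_id = paste0("roi", k), frame = f,
               amplitude = sim$ground_truth$event_amplitudes[[k]])
  }))
write.csv(gt_events, file.path(out_dir, "ground_truth_events.csv"),
          row.names = FALSE)
writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
           file.path(out_dir, "config.json"))

# a short rendered movie (first 60 s) with smooth random rigid motion
cfg_m <- sim_config(n_rois = 12, duration_s = 60, seed = 43)
sim_m <- simulate_traces(cfg_m)
rendered <- render_movie(sim_m, field_px = 64, shifts = "random", seed = 44)
write_movie(rendered$movie, file.path(out_dir, "movie.tif"))
# labeled ROI mask as 16-bit TIFF (0 background, k = ROI k)
invisible(tiff::writeTIFF(rendered$labels / 65535,
                          file.path(out_dir, "roi_labels.tif"),
                          bits.per.sample = 16L))
write.csv(data.frame(frame = seq_len(nrow(rendered$applied_shifts)) - 1L,
                     dy = rendered$applied_shifts[, 1],
                     dx = rendered$applied_shifts[, 2]),
          file.path(out_dir, "movie_true_shifts.csv"), row.names = FALSE)

cat(sprintf("simulated %d ROIs x %d frames; whisking fraction %.2f; %d true events\n",
            cfg$n_rois, sim_n_frames(cfg), mean(beh$state),
            sum(lengths(sim$ground_truth$event_frames))))
cat(sprintf("rendered movie: %d frames, 64x64 px, rigid motion up to +/-3 px\n",
            length(rendered$movie$functional)))
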