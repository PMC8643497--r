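#!/usr/bin/env Rscript
# Convert the simulated raw ROI traces to delta-F/F with the percentile
# pipeline: 5 Hz low-pass, 1000-frame 8th-percentile detrend, noise-band
# F0, per-ROI noise SD.

suppressPackageStartupMessages(library(calwhisk))

out_dir <- "results/sim"
traces <- as.matrix(read.csv(file.path(out_dir, "traces_raw.csv")))
neuropil <- as.matrix(read.csv(file.path(out_dir, "traces_neuropil.csv")))
cfg <- jsonlite::read_json(file.path(out_dir, "config.json"))

dff <- process_traces(traces, neuropil, neuropil_r = cfg$neuropil_ratio,
                      frame_rate_hz = cfg$frame_rate_hz)
dff_mat <- vapply(dff, `[[`, numeric(nrow(traces)), "dff")
write.csv(as.data.frame(dff_mat), file.path(out_dir, "dff.csv"),
          row.names = FALSE)
meta <- data.frame(
  roi_id = names(dff),
  f0 = vapply(dff, `[[`, numeric(1), "f0"),
  noise_sd = vapply(dff, `[[`, numeric(1), "noise_sd"),
  usable = vapply(dff, `[[`, logical(1), "usable")
)
write.csv(meta, file.path(out_dir, "dff_meta.csv"), row.names = FALSE)
cat(sprintf("processed %d ROIs: F0 %.1f-%.1f, noise SD (dF/F) %.4f-%.4f, %d unusable\n",
            nrow(meta), min(meta$f0), max(meta$f0), min(meta$noise_sd),
            max(meta$noise_sd), sum(!meta$usable)))
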