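#!/usr/bin/env Rscript
# Register the rendered movie on its anatomical channel, compare recovered
# motion against the generator's applied shifts, and extract neuropil-
# corrected ROI traces.

suppressPackageStartupMessages(library(calwhisk))

out_dir <- "results/sim"
movie <- read_movie(file.path(out_dir, "movie.tif"), frame_rate_hz = 10)
true_shifts <- as.matrix(read.csv(file.path(out_dir,
                                            "movie_true_shifts.csv"))[, c("dy", "dx")])

reg <- register_frames(movie, reference = 0)
err <- abs(round(reg$shifts) - true_shifts)
cat(sprintf("registration: %d/%d frames recovered exactly (max error %.2f px)\n",
            sum(rowSums(err) == 0), nrow(err), max(err)))

labels <- round(tiff::readTIFF(file.path(out_dir, "roi_labels.tif"),
                               as.is = FALSE) * 65535)
rois <- roi_set_from_labels(labels)
rois <- derive_neuropil_masks(rois, dim = dim(labels),
                              annulus_inner_px = 2, annulus_outer_px = 8)
tr <- extract_traces(reg$movie, rois)
corrected <- neuropil_correct(tr$traces, tr$neuropil, r = 0.7)
write.csv(as.data.frame(corrected),
          file.path(out_dir, "traces_extracted.csv"), row.names = FALSE)
cat(sprintf("extracted %d ROI traces (%d frames) with neuropil annuli of %d-%d px\n",
            ncol(corrected), nrow(corrected), 2, 8))
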