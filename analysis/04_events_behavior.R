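#!/usr/bin/env Rscript
# Detect calcium transients (3x noise SD for >= 1 s) and whisking epochs
# (50-frame detrend, 3x noise SD), label each transient whisking-associated
# or spontaneous, summarize per-ROI state-specific activity, and classify
# whisking-responsive ROIs.

suppressPackageStartupMessages(library(calwhisk))

out_dir <- "results/sim"
dff_mat <- as.matrix(read.csv(file.path(out_dir, "dff.csv")))
meta <- read.csv(file.path(out_dir, "dff_meta.csv"))
beh <- read.csv(file.path(out_dir, "behavior.csv"))

dff <- lapply(seq_len(ncol(dff_mat)), function(j) {
  structure(list(dff = dff_mat[, j], f0 = meta$f0[j],
                 noise_sd = meta$noise_sd[j], frame_rate_hz = 10,
                 usable = meta$usable[j], params = list()),
            class = "dff_trace")
})
names(dff) <- meta$roi_id

epochs <- detect_whisking_epochs(beh$intensity)
iou <- sum(epochs$mask & beh$state == 1) / sum(epochs$mask | beh$state == 1)
cat(sprintf("whisking: %d epochs covering %.1f%% of frames (IoU vs truth %.3f)\n",
            nrow(epochs$epochs), 100 * mean(epochs$mask), iou))

events <- detect_transients_set(dff)
events <- label_transient_states(events, epochs)
write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
write.csv(epochs$epochs, file.path(out_dir, "whisking_epochs.csv"),
          row.names = FALSE)

activity <- summarize_activity(events, epochs, roi_ids = names(dff))
responsive <- classify_whisking_responsive_set(dff, epochs)
activity <- merge(activity, responsive, by = "roi_id", sort = FALSE)
write.csv(activity, file.path(out_dir, "activity_summary.csv"),
          row.names = FALSE)

cat(sprintf("%d transients in %d/%d active ROIs (%d whisking-associated, %d spontaneous)\n",
            nrow(events), sum(activity$is_active), nrow(activity),
            sum(events$state == "whisking"),
            sum(events$state == "spontaneous")))
cat(sprintf("whisking-responsive: %d of %d classified ROIs; median angle %.0f deg\n",
            sum(activity$responsive %in% TRUE),
            sum(!is.na(activity$responsive)),
            median(activity$angle_deg, na.rm = TRUE)))
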