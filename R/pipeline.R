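#' A-syn-like variant of a control simulation config
#'
#' Scales a control configuration by the group-level effect sizes used to
#' emulate a synucleinopathy-like population: transient rates x1.5,
#' amplitudes x1.3, whisking-responsive fraction x2, and whisking-state
#' shared drive x2.
#'
#' @param control a [sim_config()] describing the control group.
#' @param rate_factor,amplitude_factor,responsive_factor,shared_factor
#'   multiplicative effects applied to the control values.
#' @return a new `sim_config`.
#' @export
asyn_config <- function(control, rate_factor = 1.5, amplitude_factor = 1.3,
                        responsive_factor = 2, shared_factor = 2) {
  cfg <- unclass(control)
  cfg$event_rate_stationary_hz <- cfg$event_rate_stationary_hz * rate_factor
  cfg$event_rate_whisking_hz <- cfg$event_rate_whisking_hz * rate_factor
  cfg$amplitude_mean <- cfg$amplitude_mean * amplitude_factor
  cfg$responsive_fraction <- min(1, cfg$responsive_fraction * responsive_factor)
  cfg$shared_drive_weight <- min(0.95, cfg$shared_drive_weight * shared_factor)
  do.call(sim_config, cfg)
}

#' Run the full analysis pipeline on one simulated experiment
#'
#' Simulates one field of view (traces + behavior), then runs the analysis
#' exactly as on real data: neuropil correction, ΔF/F processing, transient
#' detection, whisking-epoch detection from the behavior intensity trace,
#' state labeling, per-ROI activity summaries, whisking-responsiveness
#' classification, and state-restricted pairwise correlations with a
#' circular-shift null.
#'
#' @param cfg a [sim_config()].
#' @param seed seed override (defaults to `cfg$seed`).
#' @param n_shuffles shuffle repetitions for the correlation null.
#' @param use_true_epochs use the ground-truth state sequence instead of
#'   detected epochs (for component isolation in validation).
#' @return list with `sim`, `dff_set`, `events`, `epochs`, `activity`
#'   (per-ROI summary incl. responsiveness columns), `responsive`,
#'   `correlations` (per-state observed and shuffled summaries), and
#'   `experiment` (one-row data.frame of experiment-level metrics:
#'   mean/median frequencies, amplitudes, responsive fraction over all and
#'   over classified ROIs, mean/median pairwise R per state, observed and
#'   shuffled).
#' @export
run_experiment <- function(cfg, seed = cfg$seed, n_shuffles = 20,
                           use_true_epochs = FALSE) {
  sim <- simulate_traces(cfg, seed = seed)
  dff_set <- process_traces(sim$traces, sim$neuropil,
                            neuropil_r = cfg$neuropil_ratio,
                            frame_rate_hz = cfg$frame_rate_hz)
  usable <- vapply(dff_set, `[[`, logical(1), "usable")
  dff_set <- dff_set[usable]

  epochs <- if (use_true_epochs) {
    epochs_from_state(sim$ground_truth$state, cfg$frame_rate_hz)
  } else {
    detect_whisking_epochs(sim$ground_truth$behavior_intensity,
                           cfg$frame_rate_hz)
  }

  events <- detect_transients_set(dff_set)
  events <- label_transient_states(events, epochs)
  activity <- summarize_activity(events, epochs, roi_ids = names(dff_set))
  responsive <- classify_whisking_responsive_set(dff_set, epochs)
  activity <- merge(activity, responsive, by = "roi_id", sort = FALSE)

  gated <- prepare_correlation_traces(dff_set)
  whisk_mask <- whisking_associated_mask(epochs)
  active_ids <- activity$roi_id[activity$is_active]
  corr <- list()
  if (length(active_ids) >= 2) {
    g <- gated[, active_ids, drop = FALSE]
    corr$whisking <- suppressWarnings(pairwise_correlations(g, whisk_mask))
    corr$stationary <- suppressWarnings(pairwise_correlations(g, !whisk_mask))
    corr$shuffled_whisking <- suppressWarnings(
      shuffled_correlations(g, whisk_mask, n_shuffles, seed))
    corr$shuffled_stationary <- suppressWarnings(
      shuffled_correlations(g, !whisk_mask, n_shuffles, seed))
  }

  mean_or_na <- function(x) if (length(x) && any(is.finite(x)))
    mean(x, na.rm = TRUE) else NA_real_
  median_or_na <- function(x) if (length(x) && any(is.finite(x)))
    stats::median(x, na.rm = TRUE) else NA_real_
  classified <- !is.na(activity$responsive)
  experiment <- data.frame(
    n_rois = nrow(activity),
    n_active = sum(activity$is_active),
    freq_stationary = mean_or_na(activity$freq_stationary[activity$is_active]),
    freq_whisking = mean_or_na(activity$freq_whisking[activity$is_active]),
    amp_stationary = mean_or_na(activity$amp_stationary),
    amp_whisking = mean_or_na(activity$amp_whisking),
    responsive_fraction_all =
      sum(activity$responsive %in% TRUE) / nrow(activity),
    responsive_fraction_classified =
      if (any(classified)) mean(activity$responsive[classified]) else NA_real_,
    angle_sd = stats::sd(activity$angle_deg[activity$is_active], na.rm = TRUE),
    r_whisking_mean = mean_or_na(corr$whisking$r),
    r_whisking_median = median_or_na(corr$whisking$r),
    r_stationary_mean = mean_or_na(corr$stationary$r),
    r_stationary_median = median_or_na(corr$stationary$r),
    r_shuffled_whisking_mean = mean_or_na(corr$shuffled_whisking$r),
    r_shuffled_stationary_mean = mean_or_na(corr$shuffled_stationary$r)
  )

  list(sim = sim, dff_set = dff_set, events = events, epochs = epochs,
       activity = activity, responsive = responsive, correlations = corr,
       experiment = experiment)
}

#' Simulate and analyse a control vs a-syn-like group comparison
#'
#' Runs `n_experiments` independent fields of view per group (distinct
#' derived seeds), collects per-ROI and per-experiment metrics, and applies
#' the group statistics: KS on pooled per-ROI frequency, amplitude and angle
#' distributions, ranksum on per-experiment responsive fractions, KS on
#' per-experiment mean pairwise correlations per state.
#'
#' @param control_cfg control-group [sim_config()].
#' @param asyn_cfg a-syn-like [sim_config()] (default [asyn_config()] of
#'   the control).
#' @param n_experiments fields of view per group.
#' @param seed master seed.
#' @param n_shuffles shuffle repetitions per experiment.
#' @return list with `per_roi` (pooled per-ROI activity with `group`),
#'   `per_experiment` (experiment metrics with `group`), and `stats`
#'   (data.frame of group comparisons from [compare_groups()]).
#' @export
compare_experiment_groups <- function(control_cfg,
                                      asyn_cfg = asyn_config(control_cfg),
                                      n_experiments = 8, seed = 1L,
                                      n_shuffles = 10) {
  run_group <- function(cfg, label, offset) {
    rois <- list(); exps <- list()
    for (e in seq_len(n_experiments)) {
      res <- run_experiment(cfg, seed = derive_seed(seed, offset + e),
                            n_shuffles = n_shuffles)
      a <- res$activity; a$group <- label; a$experiment <- e
      x <- res$experiment; x$group <- label; x$experiment <- e
      rois[[e]] <- a; exps[[e]] <- x
    }
    list(per_roi = do.call(rbind, rois),
         per_experiment = do.call(rbind, exps))
  }
  ctl <- run_group(control_cfg, "control", 100L)
  asn <- run_group(asyn_cfg, "asyn", 200L)
  per_roi <- rbind(ctl$per_roi, asn$per_roi)
  per_exp <- rbind(ctl$per_experiment, asn$per_experiment)

  act <- function(df) df[df$is_active, ]
  stats_rows <- rbind(
    compare_groups(act(ctl$per_roi)$freq_stationary,
                   act(asn$per_roi)$freq_stationary, "ks", "freq_stationary"),
    compare_groups(act(ctl$per_roi)$freq_whisking,
                   act(asn$per_roi)$freq_whisking, "ks", "freq_whisking"),
    compare_groups(act(ctl$per_roi)$amp_stationary,
                   act(asn$per_roi)$amp_stationary, "ks", "amp_stationary"),
    compare_groups(act(ctl$per_roi)$amp_whisking,
                   act(asn$per_roi)$amp_whisking, "ks", "amp_whisking"),
    compare_groups(ctl$per_experiment$responsive_fraction_all,
                   asn$per_experiment$responsive_fraction_all,
                   "ranksum", "responsive_fraction"),
    compare_groups(act(ctl$per_roi)$angle_deg, act(asn$per_roi)$angle_deg,
                   "ks", "angle_deg"),
    compare_groups(ctl$per_experiment$r_whisking_mean,
                   asn$per_experiment$r_whisking_mean, "ks", "r_whisking"),
    compare_groups(ctl$per_experiment$r_stationary_mean,
                   asn$per_experiment$r_stationary_mean, "ks", "r_stationary")
  )
  list(per_roi = per_roi, per_experiment = per_exp, stats = stats_rows)
}
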