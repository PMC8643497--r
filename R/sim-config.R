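#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate an awake
#' GCaMP6s recording at a 10 Hz frame rate: sparse calcium transients with a
#' fast rise and ~1.5 s decay riding on a noisy, slowly drifting baseline
#' with neuropil contamination, and a two-state (whisking / stationary)
#' behavior process that modulates event rates.
#'
#' @param n_rois number of ROIs (neuronal somata).
#' @param duration_s recording length in seconds.
#' @param frame_rate_hz imaging frame rate in Hz (default 10).
#' @param event_rate_stationary_hz per-ROI transient rate during stationary
#'   epochs, events/s.
#' @param event_rate_whisking_hz per-ROI transient rate during whisking for
#'   whisking-responsive ROIs, events/s.
#' @param amplitude_mean,amplitude_sd transient amplitude distribution in
#'   dF/F units (normal, truncated at a small positive floor).
#' @param tau_rise_s,tau_decay_s rise and decay time constants (s) of the
#'   difference-of-exponentials calcium kernel; decay must exceed rise.
#' @param baseline_f baseline fluorescence level in arbitrary units.
#' @param noise_sd white-noise SD in fluorescence units.
#' @param drift_amplitude slow-drift SD in fluorescence units.
#' @param drift_timescale_s drift smoothing timescale in seconds; default
#'   180 s, bleaching/focus-drift-like, slower than the 1000-frame detrend
#'   window that is designed to remove it.
#' @param neuropil_ratio contamination coefficient in [0, 1): the measured
#'   ROI trace is the clean trace plus this fraction of the (median-centered)
#'   neuropil trace.
#' @param whisking_mean_bout_s,whisking_mean_gap_s mean whisking bout and
#'   inter-bout gap durations (s) of the alternating exponential renewal
#'   behavior process.
#' @param behavior_amplitude elevation of the whisker-video intensity trace
#'   during whisking, in units of `behavior_noise_sd` (the behavior SNR).
#' @param behavior_noise_sd behavior-trace noise SD (intensity units).
#' @param shared_drive_weight in [0, 1): fraction of whisking-state events
#'   drawn from a population-shared latent event train; the shared train
#'   substitutes for, not adds to, independent events, so per-ROI marginal
#'   rates are preserved while pairwise whisking-state correlation grows.
#' @param responsive_fraction fraction of ROIs whose event rate follows the
#'   whisking state (the rest keep the stationary rate throughout).
#' @param onset_locked_fraction in [0, 1]: fraction of a responsive ROI's
#'   whisking-rate excess concentrated in the first second of each bout
#'   (whisking-responsive neurons respond at whisking onset); the
#'   bout-averaged rate is unchanged.
#' @param seed master integer seed; all sub-streams derive from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_rois = 40,
                       duration_s = 600,
                       frame_rate_hz = 10,
                       event_rate_stationary_hz = 0.02,
                       event_rate_whisking_hz = 0.25,
                       amplitude_mean = 0.5,
                       amplitude_sd = 0.15,
                       tau_rise_s = 0.18,
                       tau_decay_s = 1.5,
                       baseline_f = 100,
                       noise_sd = 3,
                       drift_amplitude = 4,
                       drift_timescale_s = 180,
                       neuropil_ratio = 0.3,
                       whisking_mean_bout_s = 2,
                       whisking_mean_gap_s = 6,
                       behavior_amplitude = 8,
                       behavior_noise_sd = 1,
                       shared_drive_weight = 0.2,
                       responsive_fraction = 0.3,
                       onset_locked_fraction = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_rois = as.integer(n_rois), duration_s = duration_s,
    frame_rate_hz = frame_rate_hz,
    event_rate_stationary_hz = event_rate_stationary_hz,
    event_rate_whisking_hz = event_rate_whisking_hz,
    amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
    tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
    baseline_f = baseline_f, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, drift_timescale_s = drift_timescale_s,
    neuropil_ratio = neuropil_ratio,
    whisking_mean_bout_s = whisking_mean_bout_s,
    whisking_mean_gap_s = whisking_mean_gap_s,
    behavior_amplitude = behavior_amplitude,
    behavior_noise_sd = behavior_noise_sd,
    shared_drive_weight = shared_drive_weight,
    responsive_fraction = responsive_fraction,
    onset_locked_fraction = onset_locked_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_rois < 1) stop("n_rois must be >= 1")
    if (duration_s <= 0) stop("duration_s must be positive")
    if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
    if (event_rate_stationary_hz < 0 || event_rate_whisking_hz < 0)
      stop("event rates must be non-negative")
    if (amplitude_mean < 0 || amplitude_sd < 0)
      stop("amplitude parameters must be non-negative")
    if (!(tau_decay_s > tau_rise_s && tau_rise_s > 0))
      stop("kernel requires tau_decay_s > tau_rise_s > 0")
    if (baseline_f <= 0) stop("baseline_f must be positive")
    if (noise_sd < 0 || drift_amplitude < 0 || behavior_noise_sd < 0)
      stop("noise and drift SDs must be non-negative")
    if (drift_timescale_s <= 0) stop("drift_timescale_s must be positive")
    if (neuropil_ratio < 0 || neuropil_ratio >= 1)
      stop("neuropil_ratio must lie in [0, 1)")
    if (whisking_mean_bout_s <= 0 || whisking_mean_gap_s <= 0)
      stop("whisking bout and gap means must be positive")
    if (shared_drive_weight < 0 || shared_drive_weight >= 1)
      stop("shared_drive_weight must lie in [0, 1)")
    if (responsive_fraction < 0 || responsive_fraction > 1)
      stop("responsive_fraction must lie in [0, 1]")
    if (onset_locked_fraction < 0 || onset_locked_fraction > 1)
      stop("onset_locked_fraction must lie in [0, 1]")
  })
  invisible(cfg)
}

#' Number of frames implied by a simulation config
#' @param cfg a [sim_config()].
#' @return integer frame count.
#' @export
sim_n_frames <- function(cfg) {
  as.integer(round(cfg$duration_s * cfg$frame_rate_hz))
}

#' Difference-of-exponentials calcium kernel
#'
#' `h(t) = exp(-t / tau_decay) - exp(-t / tau_rise)`, sampled at the frame
#' rate and normalized so its discrete peak equals 1; an event of amplitude
#' `a` then produces a trace excursion peaking at `a`.
#'
#' @param tau_rise_s,tau_decay_s kernel time constants in seconds.
#' @param frame_rate_hz sampling rate.
#' @param length_s kernel support in seconds (default 8 decay constants).
#' @return numeric vector of kernel samples.
#' @export
calcium_kernel <- function(tau_rise_s, tau_decay_s, frame_rate_hz,
                           length_s = 8 * tau_decay_s) {
  stopifnot(tau_decay_s > tau_rise_s, tau_rise_s > 0)
  t <- seq(0, length_s, by = 1 / frame_rate_hz)
  h <- exp(-t / tau_decay_s) - exp(-t / tau_rise_s)
  h / max(h)
}
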