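#' Simulate a whisking / stationary behavior recording
#'
#' Two-state alternating renewal process: whisking bouts and inter-bout gaps
#' have exponentially distributed durations with the configured means. The
#' returned intensity trace emulates the mean pixel intensity of a whisker
#' ROI on the behavior video: baseline plus white noise plus slow drift,
#' elevated and strongly fluctuating while the animal whisks.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed override; defaults to `cfg$seed`.
#' @return list with `intensity` (numeric trace), `state` (integer vector,
#'   1 = whisking, 0 = stationary), `epochs` (data.frame of 0-based
#'   half-open whisking intervals).
#' @export
simulate_behavior <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  n <- sim_n_frames(cfg)
  fps <- cfg$frame_rate_hz
  set.seed(derive_seed(seed, 1L))

  # alternating renewal in continuous time, starting in a gap; durations are
  # shifted-exponential with a 0.5 s physiological floor (sub-half-second
  # twitches are not scored as whisking bouts), keeping the configured means
  state <- integer(n)
  t_frame <- 0L
  whisking <- FALSE
  min_s <- min(0.5, cfg$whisking_mean_bout_s / 2, cfg$whisking_mean_gap_s / 2)
  while (t_frame < n) {
    mean_s <- if (whisking) cfg$whisking_mean_bout_s else cfg$whisking_mean_gap_s
    dur_s <- min_s + stats::rexp(1, 1 / (mean_s - min_s))
    len <- max(1L, as.integer(round(dur_s * fps)))
    hi <- min(n, t_frame + len)
    if (whisking) state[(t_frame + 1L):hi] <- 1L
    t_frame <- hi
    whisking <- !whisking
  }

  drift <- slow_drift(n, cfg$drift_timescale_s * fps,
                      cfg$behavior_noise_sd * 0.5)
  noise <- stats::rnorm(n, 0, cfg$behavior_noise_sd)
  # whisker sweeps cross the ROI faster than the video rate, so in-bout
  # intensity flickers over the full range rather than sitting at a plateau;
  # the flicker is what keeps a bout's own low percentile near baseline
  whisk_sig <- state * cfg$behavior_amplitude * cfg$behavior_noise_sd *
    1.2 * stats::runif(n)
  intensity <- 50 + drift + noise + whisk_sig

  list(intensity = intensity,
       state = state,
       epochs = runs_from_mask(state == 1L))
}

#' Smoothed random-walk drift
#' @keywords internal
slow_drift <- function(n, timescale_frames, amplitude) {
  if (amplitude <= 0) return(numeric(n))
  w <- cumsum(stats::rnorm(n))
  w <- moving_average(w, max(3L, as.integer(timescale_frames)))
  w <- w - mean(w)
  s <- stats::sd(w)
  if (s == 0) return(numeric(n))
  w * (amplitude / s)
}

#' Simulate ROI and neuropil fluorescence traces with ground truth
#'
#' Per ROI, transient events are drawn from an inhomogeneous Bernoulli
#' approximation of a Poisson process whose rate follows the behavioral
#' state: whisking-responsive ROIs fire at `event_rate_whisking_hz` during
#' whisking frames and `event_rate_stationary_hz` otherwise; non-responsive
#' ROIs keep the stationary rate throughout. A fraction
#' `shared_drive_weight` of each ROI's whisking-state events is taken from a
#' population-shared latent train (thinned per ROI), the rest from an
#' independent train at the complementary rate, so the marginal per-ROI rate
#' is conserved while whisking-state pairwise correlations grow with the
#' weight. Events are convolved with the peak-normalized
#' difference-of-exponentials kernel and scaled by truncated-normal
#' amplitudes (dF/F units, converted to fluorescence via `baseline_f`).
#' White noise, slow drift, and a median-centered neuropil trace (weighted
#' by `neuropil_ratio`) are added.
#'
#' @param cfg a [sim_config()].
#' @param behavior optional output of [simulate_behavior()]; generated from
#'   `cfg` when missing so the two stay consistent.
#' @param seed optional seed override; defaults to `cfg$seed`.
#' @return list with `traces` (n_frames x n_rois matrix of measured ROI
#'   fluorescence), `neuropil` (matching neuropil trace matrix),
#'   `clean` (noise-free, contamination-free traces), and `ground_truth`:
#'   `event_frames` / `event_amplitudes` (per-ROI lists, 0-based frames),
#'   `state` (per-frame 0/1), `responsive` (per-ROI logical),
#'   `kernel_params`, `config`.
#' @export
simulate_traces <- function(cfg, behavior = NULL, seed = cfg$seed) {
  validate_sim_config(cfg)
  if (is.null(behavior)) behavior <- simulate_behavior(cfg, seed = seed)
  n <- sim_n_frames(cfg)
  fps <- cfg$frame_rate_hz
  dt <- 1 / fps
  state <- behavior$state
  stopifnot(length(state) == n)

  set.seed(derive_seed(seed, 2L))
  responsive <- stats::runif(cfg$n_rois) < cfg$responsive_fraction

  w <- cfg$shared_drive_weight
  p_stat <- min(1, cfg$event_rate_stationary_hz * dt)

  # per-frame whisking-state rate profile of a responsive ROI: a fraction
  # `onset_locked_fraction` of the rate excess over the stationary rate is
  # concentrated in the first second of each bout (whisking-responsive
  # neurons respond at whisking onset), the rest is spread over the bout;
  # the bout-averaged rate stays event_rate_whisking_hz
  profile <- rep(cfg$event_rate_stationary_hz, n)
  excess <- max(0, cfg$event_rate_whisking_hz - cfg$event_rate_stationary_hz)
  cl <- cfg$onset_locked_fraction
  onset_win <- max(1L, seconds_to_frames(1, fps))
  bouts <- behavior$epochs
  if (nrow(bouts)) {
    for (b in seq_len(nrow(bouts))) {
      idx <- (bouts$onset[b] + 1L):bouts$offset[b]
      L <- length(idx)
      W <- min(onset_win, L)
      prof_b <- rep((1 - cl) * excess, L)
      prof_b[seq_len(W)] <- prof_b[seq_len(W)] + cl * excess * L / W
      profile[idx] <- profile[idx] + prof_b
    }
  }
  p_prof <- pmin(1, profile * dt)

  # population-shared latent train with the responsive rate profile; each
  # ROI keeps a shared event with probability shared_drive_weight (thinned
  # further for non-responsive ROIs so their marginal rate is unchanged)
  shared_train <- (stats::runif(n) < p_prof) & (state == 1L)

  kern <- calcium_kernel(cfg$tau_rise_s, cfg$tau_decay_s, fps)

  traces <- matrix(0, n, cfg$n_rois)
  neuropil <- matrix(0, n, cfg$n_rois)
  clean <- matrix(0, n, cfg$n_rois)
  event_frames <- vector("list", cfg$n_rois)
  event_amplitudes <- vector("list", cfg$n_rois)

  # neuropil common component: slow + a faint copy of population activity
  set.seed(derive_seed(seed, 3L))
  np_common <- slow_drift(n, cfg$drift_timescale_s * fps / 2,
                          cfg$noise_sd)

  for (i in seq_len(cfg$n_rois)) {
    set.seed(derive_seed(seed, 10L + i))
    p_here <- if (responsive[i]) p_prof else rep(p_stat, n)
    # independent component at the complementary rate during whisking
    p_indep <- p_here
    p_indep[state == 1L] <- p_here[state == 1L] * (1 - w)
    indep <- stats::runif(n) < p_indep
    keep_prob <- w * pmin(1, p_here / pmax(p_prof, 1e-12))
    keep_shared <- shared_train & (stats::runif(n) < keep_prob)
    spikes <- indep | keep_shared
    ev <- which(spikes) - 1L # 0-based
    amp <- pmax(0.05, stats::rnorm(length(ev), cfg$amplitude_mean,
                                   cfg$amplitude_sd))
    event_frames[[i]] <- ev
    event_amplitudes[[i]] <- amp

    sig <- numeric(n)
    if (length(ev)) {
      impulse <- numeric(n)
      impulse[ev + 1L] <- impulse[ev + 1L] + amp
      sig <- stats::convolve(impulse, rev(kern), type = "open")[seq_len(n)]
    }
    clean[, i] <- cfg$baseline_f * (1 + sig)

    np <- 0.7 * cfg$baseline_f + np_common +
      slow_drift(n, cfg$drift_timescale_s * fps, cfg$drift_amplitude) +
      stats::rnorm(n, 0, cfg$noise_sd)
    neuropil[, i] <- np

    drift <- slow_drift(n, cfg$drift_timescale_s * fps, cfg$drift_amplitude)
    noise <- stats::rnorm(n, 0, cfg$noise_sd)
    traces[, i] <- clean[, i] + drift + noise +
      cfg$neuropil_ratio * (np - stats::median(np))
  }

  colnames(traces) <- colnames(neuropil) <- colnames(clean) <-
    paste0("roi", seq_len(cfg$n_rois))

  list(
    traces = traces, neuropil = neuropil, clean = clean,
    ground_truth = list(
      event_frames = event_frames,
      event_amplitudes = event_amplitudes,
      state = state,
      epochs = behavior$epochs,
      behavior_intensity = behavior$intensity,
      responsive = responsive,
      kernel_params = c(tau_rise_s = cfg$tau_rise_s,
                        tau_decay_s = cfg$tau_decay_s),
      config = cfg
    )
  )
}
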