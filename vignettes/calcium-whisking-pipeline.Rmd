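---
title: "Methods: awake calcium-imaging analysis with whisking states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: awake calcium-imaging analysis with whisking states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`calwhisk` implements an analysis chain for awake-mouse two-photon calcium
imaging referenced to whisking behavior, together with a synthetic-data
generator that provides ground truth for every stage. This vignette is the
package's account of the underlying models, the parameters that matter, the
numerical choices, and the known limitations. Every empirical number quoted
here is computed by the test suite or by `scripts/acceptance.R`; nothing is
asserted that the code does not measure.

## The recording model

The pipeline assumes a two-channel recording: a functional channel carrying
a slow genetically encoded calcium indicator (GCaMP6s-like: fast rise,
decay on the order of 1–2 s) and an anatomical channel carrying a static
red fluorophore, both sampled at 10 Hz, plus a behavior video of the snout
from which a whisker-region mean-intensity trace is derived at the imaging
frame rate. Frame indices are 0-based, intervals half-open, and
`time(frame) = frame / frame_rate_hz` throughout.

## Stage by stage

### Rigid registration

Brain displacement under head fixation is small and well approximated by
pure translation. `register_frames()` estimates a per-frame (dy, dx) by FFT
cross-correlation of each anatomical frame against a reference (mean
anatomical frame, or a chosen frame index), refines the correlation peak by
a separable three-point quadratic fit for sub-pixel precision, and applies
the negated shift to both channels. Applied shifts are rounded to integers
by default — integer translation is exactly invertible and introduces no
interpolation artifacts — with optional bilinear sub-pixel application.
Border pixels vacated by the shift are filled with the frame median, never
NaN, so downstream averaging statistics stay finite. A constant anatomical
reference (no spatial structure) degenerates; the function warns and
returns zero shifts rather than amplifying noise.

The returned shifts follow the ground-truth convention: they are the
estimated displacement of each frame *relative to the reference*, so on
synthetic movies they compare directly against the motion the renderer
applied. Only relative motion is recoverable, which is why the renderer's
random-walk motion is re-anchored to zero at the first frame.

### ROI traces and neuropil correction

ROI masks are taken as given (somata are manually outlined in this kind of
experiment; automated segmentation is out of scope). Traces are plain
per-frame means over mask pixels. Neuropil contamination is removed as

```
corrected(t) = roi(t) − r · (neuropil(t) − median(neuropil))
```

with `r = 0.7` by default and the neuropil sampled from a per-ROI annulus
(default 2–8 px from the ROI boundary) that excludes *all* ROI pixels in
the field. Median-centering the neuropil trace before subtraction is
deliberate: the correction should remove contaminating *fluctuations*
without destroying the absolute baseline level, because the ΔF/F
denominator downstream is estimated from that baseline. The annulus
geometry and `r` are exposed as parameters; neither has a canonical value
in this preparation, and results that depend sensitively on them should be
reported with the values used.

### ΔF/F and the noise band

The processing order is fixed: 5 Hz low-pass → 1000-frame sliding
8th-percentile detrend → F0 and noise estimation on the detrended trace →
ΔF/F. Three numerical decisions deserve explanation.

**The 5 Hz low-pass at a 10 Hz frame rate is the Nyquist frequency.** A
sharp 5 Hz filter on a 10 Hz recording is the identity; implementing it
that way would make the step a no-op. It is instead implemented as a
3-frame binomial kernel (1, 2, 1)/4 — unit DC gain, zero gain exactly at
Nyquist, zero phase — which is the natural reading of "low-pass at Nyquist"
for so short a kernel budget. Sub-Nyquist cutoffs (other frame rates) use a
second-order zero-phase Butterworth (`signal::filtfilt`). The choice is
recorded in the per-trace parameter provenance.

**The 1000-frame detrend preserves the baseline level.** Subtracting a
sliding window percentile literally would zero the baseline, leaving
nothing for F0 to estimate and making ΔF/F divide by noise. The pipeline
therefore subtracts the sliding 8th percentile and adds back the median of
the removed trend: slow fluctuations are flattened, the absolute level
survives. The exported `detrend()` primitive performs the literal
subtraction by default (`keep_baseline = FALSE`) so it can also serve the
behavior-trace path, where no baseline is needed.

**The noise band and its SD.** The noise band is the residual after
subtracting a 1-s sliding 8th percentile. F0 is the median of the trace
over frames whose noise-band value lies at or below the band's 70th
percentile; the noise SD is the SD of the band over those same frames.
Restricting both statistics to sub-70th-percentile frames makes them robust
to transients. Two consequences are documented and tested rather than
hidden:

* this F0 is deliberately conservative — conditioning on locally low
  samples places it ~0.35 raw-noise SD below the true baseline, so
  event-free ΔF/F has a small positive mean (far below any 3×SD detection
  threshold);
* the truncated noise SD underestimates the raw noise SD; every threshold
  in the pipeline is defined in units of *this* SD, consistently, so the
  operating points are internally coherent.

Percentiles everywhere use linear interpolation between order statistics
(`quantile` type 7), fixed because an 8th percentile over short windows is
sensitive to the convention. Sliding windows are centered and truncated at
the edges: early and late frames use shorter windows rather than fabricated
padding. Traces whose F0 is non-positive are flagged unusable and excluded
with a log message, since ΔF/F is undefined for them. The sliding
percentile is the computational hot spot and is implemented in C++ with an
incrementally maintained sorted window (exact, not approximated).

### Transients, whisking epochs, and association

A transient is a maximal run of frames with ΔF/F above 3× the noise-band
SD lasting at least 10 frames (1 s); an ROI with at least one transient is
"active". The behavior trace is detrended with a 50-frame sliding 8th
percentile; because that residual sits above zero even at rest, it is
centered on its own quiet-frame baseline (the F0 analog) before applying
the 3×SD whisking threshold — exactly the centering the fluorescence path
gets via ΔF/F. Whisking epochs separated by fewer than 5 frames (0.5 s)
are merged and epochs shorter than 3 frames dropped; both values are
exposed parameters with no canonical published value.

A transient is whisking-associated iff its onset lies within
`[epoch_start − 1 s, epoch_end + 2 s)`; all others are spontaneous. Events
are assigned by onset only (an event straddling a boundary is not split).
The same margins define whisking-associated *time* in the frequency
denominators, so state-specific frequencies are honest rates: the
numerator's window and the denominator's window coincide. The activity
angle is `atan2(freq_whisking, freq_stationary)` in degrees — 0° means
activity exclusively during stationary epochs, 90° exclusively
whisking-associated.

### Whisking responsiveness

Per whisking onset, the response is the mean ΔF/F over (+0.5 s, +1.5 s]
and the baseline the mean over [−0.5 s, 0). The paired test across onsets
is a one-sided Wilcoxon signed-rank at α = 0.05 by default (no normality
assumption for single-trial calcium responses; a paired t-test is
available). ROIs with fewer than 5 usable onsets are left unclassified
rather than silently negative. Onsets within 2 s of the recording start are
excluded (incomplete baseline), as are onsets whose response window leaves
the recording. The onset-aligned matrix normalizes each segment by its own
pre-onset baseline mean — the convention used for population heat maps.

### Transient kinetics

Kinetics are computed on isolated transients: events not *followed* by
another event of the same ROI within 10 s (forward-looking, exactly as the
rule is stated; a preceding event does not disqualify, but segments whose
1-s pre-onset baseline overlaps a previous event are dropped to protect the
normalization). Onsets come from the first derivative of the 7-frame
moving-average-smoothed trace exceeding 3.5× the derivative's baseline SD,
the baseline being all frames outside detected transients — a definition
the thresholding rule needs but that is rarely spelled out. Segments are
aligned at onset, baseline-subtracted, averaged; the decay time is the
first post-peak crossing of 36.8% of the peak and the half-decay time the
50% crossing, both located by linear interpolation between frames (at 10 Hz
a frame is 100 ms — too coarse for comparing decay constants otherwise).

Validation uses fast-rise kernels (τ_rise = 0.02 s, within one frame at
10 Hz) so the post-peak decay is effectively mono-exponential, the regime
in which "time to 36.8%" equals τ and the half-decay/decay ratio equals
ln 2. With the generator's default τ_rise = 0.18 s the
difference-of-exponentials peak shifts late and the measured post-peak
decay time exceeds τ by >10% at τ = 0.5 s — a property of the metric, not
an estimator error. Similarly, the 5 Hz low-pass attenuates the peak of
very fast transients (~16% at τ_decay = 0.5 s), so amplitude-recovery
checks are meaningful only for τ ≥ 1 s.

### Pairwise correlations and the circular-shift null

Traces are smoothed over 25 frames, gated to exactly zero below 2× the
noise-band SD, and Pearson-correlated over state-restricted frames for all
unordered pairs of active ROIs — zero-inflation and all, exactly as the
procedure is defined; no rank-based substitute is made. The whisking state
mask includes the same 1 s / 2 s margins as event labeling; stationary is
its complement. Pairs in which either trace is constant on the state's
frames have undefined R and are excluded but counted. States shorter than
50 frames are skipped with a warning.

The surrogate null circularly shifts each ROI's *full-length* gated trace
by an independent uniform offset in [1, n_frames] before state
restriction — shifting preserves each trace's autocorrelation and marginal
distribution while destroying cross-trace alignment, and shifting before
restriction keeps the surrogate's temporal structure intact. The default is
100 shuffles, pooled; the seed is logged.

One quantitative caveat matters when interpreting per-pair null values:
smoothing over 25 frames gives the null R a variance floor —
`sd(R) ≈ sqrt((1 + 2·Σ ρ_k²) / n)` ≈ 0.076 at n = 6000 frames — so the
mean *absolute* null correlation is ~0.06 no matter how independent the
traces are. The meaningful validity property of the null is that it is
*unbiased* (mean R ≈ 0, measured at ~10⁻³) and reproducible under a fixed
seed; detecting a correlation excess requires pooling pairs or experiments,
not per-pair thresholds.

### Group statistics

Distribution comparisons use Kolmogorov–Smirnov (pooled per-ROI
frequencies, amplitudes, angles, correlation distributions), location
comparisons on non-normal per-experiment metrics use the ranksum
(Mann–Whitney) test (responsive fractions), and normal averages use
Student's t-test. Direction is reported as the sign of the median
difference.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, at
the study's recording conditions (10 Hz, 600-s fields of view), with full
ground truth: true event frames and amplitudes, the true behavioral state
sequence, kernel parameters, responsiveness assignments, and — for rendered
movies — applied rigid shifts and ROI centroids. All randomness derives
from one master seed through a documented splitting scheme
(`derive_seed(seed, stream)`), so sub-streams are independently
reproducible.

**Behavior.** Whisking is an alternating renewal process with
exponentially distributed bout and gap durations (defaults 2 s and 6 s,
whisking fraction 0.25). Durations carry a 0.5-s physiological floor
(shifted exponential, means preserved): sub-half-second twitches are not
scored as whisking bouts by behavioral convention, and a frame-rate-limited
detector could never recover them anyway. The bout statistics are
placeholders in the sense that no published values constrain them. The
whisker-ROI intensity trace *flickers* across its full range during a bout
(uniform multiplier on the bout amplitude, default SNR 8) rather than
sitting at a plateau — whisker sweeps cross the video ROI faster than the
frame rate — and that flicker is precisely what keeps a bout's own sliding
8th percentile near baseline so the 50-frame detrend does not swallow long
bouts.

**Events and traces.** Per ROI, events follow a Bernoulli-per-frame
approximation of an inhomogeneous Poisson process. Responsive ROIs (a
configurable fraction, default 0.3) follow the whisking state: default
0.25 events/s during whisking vs 0.02 events/s otherwise, with a fraction
(default 0.6) of the whisking-rate *excess* concentrated in the first
second of each bout. The onset concentration reflects how
whisking-responsive somatosensory neurons actually behave — they respond at
whisking *onset* — and is what makes responsiveness detectable by an
onset-aligned test at all; the bout-averaged rate is unchanged. A
population-shared latent train during whisking, thinned per ROI with weight
`shared_drive_weight` (default 0.2), substitutes for (never adds to)
independent events, conserving marginal rates while creating
whisking-state pairwise correlation. Events are convolved with a
peak-normalized difference-of-exponentials kernel (defaults τ_rise 0.18 s,
τ_decay 1.5 s, GCaMP6s-like) and scaled by truncated-normal amplitudes in
ΔF/F units (default 0.5 ± 0.15). Traces add white noise (default SD 3 on a
baseline of 100, i.e. 3% of baseline), a slow random-walk drift smoothed to
a 180-s timescale, and neuropil contamination mixed exactly the way the
correction removes it. The drift timescale is deliberately slower than the
1000-frame (100-s) detrend window: percentile detrending is designed for
bleaching- and focus-like drift; drift sharing the transients' own
timescale is not removable by any baseline method and is not part of the
model.

**Group effects.** An "a-syn-like" configuration scales the control: event
rates ×1.5, amplitudes ×1.3, responsive fraction ×2, whisking shared drive
×2 — the effect directions the pipeline is expected to resolve.
`compare_experiment_groups()` simulates independent fields of view per
group (distinct derived seeds) and applies the group statistics above.

**Movies.** ROIs render as 2-D Gaussian spots at non-overlapping random
centroids; the functional channel follows each ROI's clean trace, the
anatomical channel is static spots plus noise, and optional rigid shifts
(integer or fractional, recorded in ground truth) apply to both channels
identically. Pixel values are clamped non-negative (photodetector counts)
and serialized as 32-bit-float multi-page TIFF on a fixed intensity scale.

## What the validation does and does not show

The test suite and `scripts/acceptance.R` verify, at the study's recording
conditions: exact recovery of integer rigid motion and ≤0.25-px recovery of
0.5-px motion on rendered movies; ΔF/F = 0.5 ± 10% for a transient from
baseline 100 to peak 150 through the full percentile pipeline (and exact
zeros on constants); transient detection recall and precision ≥ 0.9 for
5×-noise-SD events at 0.05 Hz (event-level matching: a true event counts as
recalled when it falls within ±3 frames of a detected episode's span, an
episode as correct when it contains a true event — episodes legitimately
span multiple true events closer than the indicator decay); whisking-state
IoU ≥ 0.9 at video SNR 8; decay-time recovery within 10% and
half-decay/decay within 5% of ln 2 over τ ∈ {0.5, 1, 1.5, 2.5} s; a
responsiveness false-positive rate at or below the 0.05 test level on 200
state-independent ROIs and ≥90% detection of 50 strongly responsive ROIs
(stationary rate 0.3 Hz, onset-locked ×5); an unbiased, seed-reproducible
shuffle null; and, on 8-vs-8 simulated fields of view, significantly higher
frequency, amplitude, responsive fraction, whisking-shifted angle
distribution, and whisking-state correlation in the a-syn-like group, with
both groups' whisking correlations exceeding their shuffled nulls.

Problem sizes (600-s recordings, 8 experiments per group, 100 shuffles,
64×64-px movies) were chosen as the smallest at which every statistical
check has comfortable power; they are stated here so results are
reproducible, and all are parameters.

Two honest limitations:

* **Stationary-correlation leak.** Whisking-shared transients decay for
  several seconds and the stationary mask begins 2 s after each epoch ends,
  so a small fraction of shared signal lands in stationary frames. With the
  generator's otherwise perfectly uncorrelated, between-experiment-identical
  stationary periods, even this small leak separates the groups' stationary
  correlations statistically — a contrast the original experiments did not
  show, plausibly because real recordings carry baseline stationary
  correlation structure and between-animal variability that this generator
  deliberately omits. The group-comparison test records this as a known
  failing sub-check rather than papering over it.
* **What passing says about real data.** The generator draws white noise,
  renders idealized Gaussian somata, uses a single fixed kernel per
  recording, and omits: shot-noise scaling with brightness, non-rigid
  motion, overlapping/merging somata, slow arousal states, and indicator
  nonlinearity (supralinear summation at high rates). Passing recovery
  tests here demonstrates the *procedures* are implemented correctly and
  are calibrated at realistic SNR; it does not certify performance on any
  particular real dataset.
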