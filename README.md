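# calwhisk

Analysis of awake-mouse two-photon calcium imaging referenced to whisking
behavior. The package takes registered two-channel recordings (a GCaMP6s-like
functional channel and a static anatomical channel at 10 Hz) plus a
whisker-video intensity trace, and produces per-neuron activity metrics,
whisking-responsiveness classifications, transient kinetics, and
state-restricted pairwise correlations with circular-shift surrogate nulls.
It is aimed at studies that compare these metrics between groups — for
example cortical hyperreactivity phenotypes in neurodegeneration models —
and at anyone who needs a tested, ground-truth-validated implementation of
this common analysis chain.

Because raw imaging data of this kind is rarely public, the package includes
a first-class synthetic-data generator (`sim_config()`, `simulate_traces()`,
`render_movie()`) that emulates the signal structure the analysis assumes —
state-dependent transient rates, shared population drive during whisking,
drifting noisy baselines, neuropil contamination, rigid motion — with
complete ground truth, so every stage is verifiable by simulation.

## The analysis in brief

For each ROI with raw trace F(t), neuropil trace N(t):

- **Neuropil correction** F_c = F − r·(N − median N), r = 0.7 by default.
- **ΔF/F**: 5 Hz low-pass; slow fluctuations removed by a sliding
  8th-percentile subtraction (1000-frame window, baseline level preserved);
  the *noise band* is the residual after a 1-s sliding 8th-percentile
  subtraction; F0 = median of samples whose noise-band value is at or below
  the band's 70th percentile; σ = SD of the band over those frames;
  ΔF/F = (F − F0)/F0.
- **Transients**: maximal runs with ΔF/F > 3σ lasting ≥ 10 frames (1 s).
- **Whisking epochs**: behavior trace detrended (50-frame sliding 8th
  percentile), thresholded at 3× its noise-band SD; epochs merged across
  gaps < 0.5 s. A transient is *whisking-associated* iff its onset lies in
  [epoch start − 1 s, epoch end + 2 s); otherwise *spontaneous*. The
  activity angle is α = atan2(freq_whisking, freq_stationary): 0° =
  exclusively stationary activity, 90° = exclusively whisking-associated.
- **Responsiveness**: per whisking onset, mean ΔF/F in (+0.5 s, +1.5 s]
  vs mean in [−0.5 s, 0); one-sided paired Wilcoxon across onsets, α = 0.05.
- **Kinetics**: isolated transients (no follower within 10 s), onsets from
  the 7-frame-smoothed derivative exceeding 3.5× its baseline SD; aligned,
  baseline-normalized averages give the peak, the decay time (to 36.8% of
  peak) and the half-decay time (to 50%), interpolated between frames.
- **Correlations**: traces smoothed over 25 frames, gated to 0 below 2σ;
  Pearson R per active-ROI pair, separately over whisking-associated and
  stationary frames; nulls from circularly shifting each full-length trace
  by a uniform offset in [1, n].

## Worked example

The `analysis/` directory is a numbered workflow over one simulated field
of view (30 ROIs, 600 s) plus a control vs a-syn-like group comparison.
Running it end to end:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_register_extract.R
Rscript analysis/03_process_traces.R
Rscript analysis/04_events_behavior.R
Rscript analysis/05_kinetics.R
Rscript analysis/06_correlations.R
Rscript analysis/07_group_comparison.R
```

prints, among other things:

```
simulated 30 ROIs x 6000 frames; whisking fraction 0.24; 847 true events
registration: 600/600 frames recovered exactly (max error 0.00 px)
processed 30 ROIs: F0 97.7-102.7, noise SD (dF/F) 0.0096-0.0128, 0 unusable
whisking: 76 epochs covering 23.9% of frames (IoU vs truth 0.923)
629 transients in 30/30 active ROIs (482 whisking-associated, 147 spontaneous)
whisking-responsive: 6 of 30 classified ROIs; median angle 64 deg
decay time 1.76 +/- 0.15 s; half-decay/decay ratio 0.735 (ln 2 = 0.693)
435 active-ROI pairs; whisking mean R 0.036 vs stationary 0.003 and null 0.0000
8 of 8 metrics significantly higher in the a-syn-like group (p < 0.01)
```

Reading these: the registration recovered the generator's rigid motion
exactly; F0 sits at the simulated baseline of 100 and the noise floor at
~1% ΔF/F; detected whisking epochs overlap the true behavioral state at
IoU 0.92; most transients are whisking-associated because responsive ROIs
concentrate events at bout onsets; the measured decay time (1.76 s) exceeds
the generating τ = 1.5 s as expected for a kernel with a 0.18-s rise (the
vignette explains why); and the group comparison reproduces the expected
effect directions, with the stationary-correlation caveat discussed in the
vignette. Tables land under `results/sim/` and `results/groups/`.

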