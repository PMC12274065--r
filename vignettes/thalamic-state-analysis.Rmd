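---
title: "Methods: thalamic firing modes and loss-of-movement scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thalamic firing modes and loss-of-movement scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalamostate)
```

## What the package measures

Thalamic relay neurons fire in two modes. In the depolarized, awake regime
they fire single spikes at fairly regular intervals (tonic mode). After
membrane hyperpolarization — during NREM sleep or under sedatives —
low-voltage-activated T-type calcium channels de-inactivate and produce
low-threshold calcium spikes crowned by clusters of 2–5 action potentials
at very short inter-spike intervals (burst mode). The behavioral
counterpart studied here is ethanol-induced sedation on a forced walking
task: a mouse walks on a slow treadmill, receives an intraperitoneal
injection, and its motion signal is scored for episodes of loss of
movement (LOM), the continuous analog of the loss-of-righting-reflex
assay.

The package implements both arms of the analysis — spike-train analytics
(burst detection, autocorrelogram indices, per-state firing metrics,
wake-referenced Z-scores, peristimulus responses to stimulation pulses)
and the motion-to-LOM classifier — plus a seeded synthetic-data generator
so every stage can be tested against known ground truth without animal
recordings.

## Burst detection

A burst is a maximal run of at least `min_spikes` (default 2) spikes whose
consecutive ISIs are all at most `isi_max_ms` (default 10 ms) and whose
first spike is preceded by at least `silence_min_ms` (default 50 ms) of
silence. The silence requirement encodes the biophysics: T-type channels
must de-inactivate during a quiet, hyperpolarized period before they can
fire a low-threshold burst. The three criteria are exposed as arguments of
`detect_bursts()` because the choice of 10/50 ms is a convention; the
defaults cohere with the analysis windows used by the two autocorrelogram
indices below (peak within 0–10 ms, baseline/denominator beyond 40–50 ms).
Burst and tonic spikes always partition the train exactly, and the test
suite holds the detector to an independent brute-force scan of the same
criteria on a thousand randomized trains.

Two summary indices are computed from the 1-ms autocorrelogram
(one-sided, zero-lag excluded, raw pair counts — the indices are count
ratios, so rate normalization cancels):

* **burst index** (`burst_index()`): peak count over lags 1–10 ms minus the
  mean count over 40–50 ms; a positive amplitude is normalized by the
  peak, a negative one by the baseline, giving a value in [-1, 1]. The
  peak is read literally as the maximum single bin (earliest lag on ties).
* **bursting ratio** (`bursting_ratio_index()`): summed counts below 10 ms
  over summed counts above 50 ms. An empty denominator returns `Inf` with
  a diagnostic rather than failing, since non-bursting, low-rate units can
  legitimately have empty long-lag windows in short recordings.

Both are kept as distinct operations; they answer the same question at
different granularity and neither is derivable from the other.

## Per-state firing metrics and classification

`state_firing_metrics()` computes, per unit and state label, the total,
tonic (non-burst) and burst-spike rates over the *occupied* state duration
(summed epoch lengths), the burst event rate per minute (events attributed
to the epoch containing their onset), and the burst-to-total spike ratio.
Both tonic and total rates are always emitted because the field uses
"tonic firing" loosely for either. A unit is flagged bursting in a state
when it exceeds one burst event per 10 minutes (strict inequality;
configurable), a deliberately permissive threshold that separates
burst-capable from burst-free units rather than grading burstiness.

Cell types follow the standard width split: regular-spiking (RS) iff the
peak-to-valley waveform width strictly exceeds 250 µs, narrow-spiking
otherwise. Epochs are half-open `[start, end)` everywhere, so a spike at
an epoch boundary is counted exactly once.

`zscore_vs_wake()` expresses a unit's firing in a target state in SD units
of its home-cage wake firing. Wake epochs are discretized into 10-s bins
(full bins only) and the bin-rate mean and SD form the reference; the
binned SD is a design choice — no bin size makes the SD of "wake firing"
well defined without one — and the bin width is an argument. Labels use
the two-sided 5% normal bounds: increase above +1.96, decrease below
-1.96, no change between.

## Motion signal to LOM metrics

The behavioral pipeline mirrors standard actigraphy practice:

1. **Filtering** (accelerometer mode): zero-phase fifth-order Butterworth
   band-pass, 0.5–20 Hz, applied forward and backward per axis
   (`filter_accelerometer()`). This removes the gravity/DC component with
   no group delay; channels are demeaned first so filter edge transients
   cannot re-inject DC.
2. **Instantaneous activity**: the across-axis RMS of the filtered x/y/z
   channels, or the per-frame video motion scalar (frame differencing,
   3×3 median filtering and displaced-pixel counting are available as
   `video_frame_activity()` for callers holding raw frames).
3. **Windowed index**: mean × SD of the activity in 4-s windows with 50%
   overlap, anchored at the first sample. The product scores sustained
   activity *and* its variability, so both stillness and a constant
   sensor offset map to zero.
4. **Normalization** (`normalize_index()`): affine map sending a cessation
   floor to 0 and the pre-injection walking baseline mean to exactly 1.
   The floor is the 1st percentile of the raw index over the whole
   recording — robust when no perfectly still segment exists — and the
   map is clipped at 0. Because the map is affine in the raw index and
   every pipeline step up to it is homogeneous in the input gain, the
   normalized index, the state labels and all LOM metrics are invariant
   under any positive rescaling of the raw motion trace.
5. **Classification** (`classify_states()`): windows are walking by
   default; maximal runs below the lower bound of the baseline's 95%
   confidence band lasting ≥ 60 s become non-walking, and within them,
   maximal sub-runs below 0.25 lasting ≥ 30 s become LOM. The baseline
   bound is the empirical 2.5th percentile of baseline windows by default
   (the index is positive and right-skewed, so a distribution-free bound
   avoids a normality assumption); a parametric mean − 1.96 SD variant is
   selectable. The 0.25 threshold applies to the normalized index, whose
   baseline averages 1 by construction. Episode boundaries snap to the
   2-s window step, so boundary placement is accurate to one step, and
   sub-threshold runs separated by a single supra-threshold window are
   *not* merged — determinism is preferred over emulating manual video
   curation.
6. **Metrics** (`lom_metrics()`): latency from injection to the first LOM
   onset at or after injection, that episode's duration, and total LOM
   time clipped to a 3600-s horizon. Absent LOM yields missing values,
   never zeros.

## Stimulation protocols

`tonic_protocol()` (default 50-ms inter-pulse interval, i.e. 20 Hz — a
wake-like thalamic rate), `burst_protocol()` (default 4 pulses at 4-ms
spacing, 250 Hz within the burst, one burst per second) and
`phasic_onoff_protocol()` (default 1 s ON / 1 s OFF, 50% duty) build
non-overlapping pulse trains on a protocol clock starting at zero; callers
shift onsets into session time. Pulse width is always explicit (the
optogenetic experiments use 6.25-ms light pulses, electrical stimulation
commonly 100-µs pulses), and every constructor validates that widths fit
inside the relevant inter-pulse interval. `peristimulus_histogram()`
summarizes evoked responses as a 1-ms latency histogram with fidelity
(fraction of pulses evoking ≥ 1 spike in the window), median first-spike
latency and first-spike jitter (SD).

## The synthetic generator: what it emulates, and what it does not

`gen_spike_train()` composes, per scheduled state epoch:

* **Tonic spikes** as a dead-time renewal process: after each spike the
  unit is silent for `tonic_min_isi_ms` (default 12 ms), then fires with
  constant hazard λ/(1 − λd), which makes the long-run rate equal the
  requested `tonic_rate_hz` exactly. The dead time is the deliberate
  modelling choice here: tonic-mode relay firing in vivo is refractory and
  quasi-regular, and placing the entire tonic ISI distribution above the
  10-ms burst criterion keeps the two firing modes in disjoint ISI
  regimes. A memoryless (Poisson) tonic process would instead produce
  chance sub-10-ms ISI pairs after 50-ms gaps at a rate of several events
  per minute even at 3 Hz — indistinguishable from genuine bursts under
  *any* ISI-based detector, and unlike real tonic firing.
* **Burst events** as a Poisson process of onsets, thinned so consecutive
  bursts are at least `pre_burst_silence_ms` (default 100 ms) apart; each
  burst gets 2–5 spikes at intra-burst ISIs drawn from 3–5 ms, and tonic
  spikes within the pre-burst window or the burst span are removed. Every
  planted burst therefore satisfies the detector's criteria by
  construction, and the thinned onset list is attached as ground truth.
  The thinning removes about 1% of candidate onsets at the NREM default
  rate, a bias well inside the sampling error of the recovery tests.

Default WT burst event rates are wake 0.16, fLOM 0.79 and NREM 5.76
events/min — the reported state averages for bursting thalamic units —
with the remaining states set to small values of the same order. Per-state
tonic rates (walk/wake 20 Hz, REM 8 Hz, fLOM/LOM 5 Hz, NREM 3 Hz) are free
parameters chosen once to reproduce the qualitative ordering of firing
with arousal; no published per-state absolute rates exist to pin them.
KO-like units have every burst rate forced to zero.

`gen_motion_trace()` builds a positive envelope: a walking baseline with
autocorrelated fluctuation (white noise smoothed over 0.5 s, relative SD
0.2) and planted episodes at a quiescent sensor-noise floor of 2% of the
baseline mean. In accelerometer mode the envelope rides on three
stride-like 3-Hz sinusoidal carriers phased 120° apart, so the across-axis
RMS at each sample equals the envelope exactly.

What the generator does **not** emulate: slow drifts and artifacts in real
accelerometry, grooming and postural transitions that produce intermediate
activity levels, non-stationary firing rates within a state, spike-sorting
contamination, and the gradual (rather than planted, step-like) onset of
sedation. Passing recovery tests therefore demonstrates that the
estimators implement their definitions and recover truth under the stated
statistical model — not that the thresholds are optimal for any particular
recording rig.

## Numerical choices and degenerate inputs

* Autocorrelogram bin k covers lags [k − 0.5, k + 0.5) ms; lags under
  0.5 ms land in no bin. The bursting-ratio windows "< 10 ms" and
  "> 50 ms" are bins 1–9 and 51–max, leaving the straddling bins out of
  both.
* A flat autocorrelogram has burst index exactly 0; an all-zero one
  returns 0 with a warning. Zero wake-rate SD makes the Z-score undefined
  (`NA` + warning) rather than infinite.
* The Levene stage is the classic mean-centered variant (absolute
  deviations from group means), delegated to `car::leveneTest(center =
  mean)`; Holm decisions use `stats::p.adjust`, and rank tests use
  `stats::wilcox.test`.
* `state_space_embedding()` projects the column-standardized firing
  features (tonic rate, burst-spike rate, burst event rate) onto their
  first two principal components with a fixed sign convention. A linear
  projection was chosen over neighbor-graph manifold methods: it is
  deterministic, seed-stable by construction, and three standardized
  features rarely support more structure than their leading plane. The
  `seed` argument is kept for interface stability.
* All times are seconds from recording start; all intervals are half-open;
  TSV/CSV dialects are fixed (tab for tables, comma for motion) with
  required headers, and unknown epoch labels are rejected rather than
  dropped.

## Problem sizes in the shipped tests

The test suite works at desk scale, chosen as the smallest sizes at which
the statistical assertions are sharp: 1000 random trains of up to 200
spikes for detector/oracle equivalence, 200 ten-minute trains per state
for burst-rate recovery (mean within 3 SEM of the planted rate), 50
seeded motion traces with two planted episodes each for LOM recovery
(boundaries within one 2-s window step), and 1000 replicates of n = 100
per group for the Levene type-I calibration (0.05 ± 0.02).

## Known limitations

States are inputs here: sleep staging, spike sorting and EEG/LFP
spectral analysis are out of scope. The LOM classifier does not replicate
manual video verification, so against hand-curated scorings it will split
episodes that a curator would bridge. The burst detector is purely
ISI-based; it cannot separate genuine low-threshold bursts from
high-frequency tonic discharge in units whose tonic ISIs dip below 10 ms
(fast-spiking interneurons), which is why width-based RS/NS classification
is applied first in population analyses.
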