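---
title: "Identifying and removing physiological noise from EPI phase and magnitude"
author: "prepair package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and removing physiological noise from EPI phase and magnitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepair)
```

## The problem

Respiration and the cardiac cycle are the dominant structured noise sources
in BOLD fMRI, especially at high field. Chest motion changes the local B0
field (a phase-sensitive effect), and pulsatile blood flow and spin-history
effects modulate the magnitude signal. Data-driven correction at the volume
repetition time fails whenever the cardiac rate (~1 Hz and above) exceeds
the volume Nyquist rate — at TRvol = 2 s anything above 0.25 Hz is aliased.

This package implements an unsupervised estimator of respiratory and cardiac
noise waveforms that needs no external recordings. Its three ideas are:

1. **Sub-TR sampling.** Every slice (or SMS excitation group) is acquired at
   a different time within the TR. Averaging each slice over high-SNR
   voxels and reordering the per-slice time series by acquisition time
   yields one scalar series of length `NR * NS` at rate `NS / TRvol`
   (`NS = N / MB` excitations per TR), on which typical cardiac rates are
   critically sampled.
2. **Phase and magnitude as complementary sources.** The phase of the
   complex EPI signal is highly sensitive to respiration-driven field
   changes; the magnitude carries the stronger cardiac signature. Both are
   processed in parallel and the better source per noise type is chosen
   automatically.
3. **Spectral hygiene before peak picking.** The reordering step turns any
   slice-dependence of a low-frequency signal into amplitude modulation of
   a carrier at `1/TRvol`, creating sidebands `k/TR ± f_m` from modulators
   such as respiration and the scanner's cold-head helium pump. These
   predicted lines are zeroed (not filtered) before the cardiac peak
   search, so a sideband that is stronger than the true cardiac line cannot
   be mistaken for it.

## The procedure

Given 4D magnitude (and optionally phase) images and the acquisition
parameters:

* **Masking.** Voxels whose temporal-mean magnitude exceeds 20% of the
  robust maximum (98th percentile of the temporal-mean image,
  linear-interpolation convention) are retained. The percentile is taken
  over the temporal-mean image — one value per voxel — rather than over all
  voxel-time samples; the two readings differ only through temporal noise,
  and the per-voxel reading matches the "mean intensity over time"
  criterion directly (`computeHighSnrMask(..., on = "all")` switches to the
  other reading). A fixed-intensity mode (`computeThresholdMask`, default
  3000) supports partial-coverage acquisitions such as brainstem slabs.
* **Slice averaging.** Magnitude: plain mean over masked voxels per slice
  and time point. Phase: magnitude-weighted mean, which suppresses
  low-signal voxels whose phase is essentially noise. Slices with empty
  masks are filled from the nearest covered slice with a warning, so
  partial-coverage runs proceed unattended.
* **Detrending.** A third-order polynomial over the full run is fitted and
  subtracted per slice, removing the slice-dependent baseline (coverage and
  tissue composition) and slow drift. This is what collapses the reordering
  carrier at `1/TR`: after detrending, per-slice constant offsets are gone,
  while genuine amplitude modulation (and hence the sidebands) remains.
* **Reordering.** Simultaneously excited slices are averaged (unweighted)
  and the `NS` group series are interleaved by excitation time. Excitations
  are assumed uniformly spaced at `TRvol/NS` with zero dead time unless
  explicit offsets are supplied; sequential ascending order with SMS group
  `g = {g, g+NS, ...}` is the default, and any other order can be given
  explicitly.
* **Identification.** Respiration first: a zero-phase second-order
  Butterworth band-pass (default 9–30 cpm) and a peak search on the
  periodogram. Then, for phase data, the pump line is sought in
  0.08–0.2 Hz (see below). Cardiac last: the band (default 42–96 bpm) is
  widened by 10% at both edges so unusual rhythms are not cut off, the
  sidebands `k/TR ± f_R` and `k/TR ± f_pump` are zeroed with notches of
  halfwidth `max(2 bins, 0.01 Hz)`, and the highest remaining peak wins.
  Peaks are refined by parabolic interpolation on log power, giving sub-bin
  frequency estimates. Zeroing is used instead of notch filtering because a
  genuine cardiac line can lie very close to a sideband; a filter would
  attenuate it, a zeroed bin does not.
* **Narrowband extraction.** The identified fundamentals are isolated with
  zero-phase band-passes of halfwidth 2.5 cpm (respiration) and 6.5 bpm
  (cardiac) — the typical spread of natural breathing and heart rates.
  Zero-phase (forward–backward) filtering is used throughout so waveform
  timing stays aligned with the slice clock.
* **Source selection.** Each candidate waveform is expanded into
  two-harmonic Fourier regressors of its cycle phase and scored by the
  fraction of variance it explains in its own source's sub-TR trace; the
  larger score wins per noise type. Scoring each candidate against its own
  source measures how much physiological variance that source actually
  carries. Scoring both against the magnitude trace — which is also
  supported (`selectSource(..., phaseTarget = NULL)`) — is degenerate: the
  magnitude-derived candidate is band-pass filtered *from* the magnitude
  trace, so it always explains that trace's own in-band noise and would win
  even when the phase carries all of the physiological signal. Exact ties
  break to phase for respiration and magnitude for cardiac, the typical
  winners in practice.
* **Cycle phases and regressors.** Cardiac phase grows linearly from 0 to
  2π between successive peaks of the narrowband waveform (peaks: local
  maxima with minimum separation `0.5/f0` and prominence above 0.25 of the
  RMS amplitude, parabolically refined). Respiratory phase uses the
  amplitude-histogram convention `φ = π·H(a)·sgn(da/dt)` mapped into
  `[0, 2π)`, which distinguishes inhalation from exhalation at equal chest
  amplitude. Each slice's regressor block is the sine and cosine of the
  first two harmonics of both phases evaluated at that slice's own
  acquisition times (8 columns); SMS partners share identical blocks.
* **Correction.** Per slice, the physiological columns are orthogonalized
  against an intercept-plus-cubic drift basis, each masked voxel is
  regressed on the joint design, and only the fitted physiological part is
  subtracted. The drift basis is *fitted but retained* in the data: the
  correction is meant to alter only physiological content, and
  orthogonalization guarantees the corrected variance can never exceed the
  original. A consequence worth knowing: if a voxel is exactly a regressor
  plus a constant, the regressor's (small) drift-basis component remains in
  the data after correction.

## Pump-line detection

The cold-head helium pump produces a narrowband line (near 0.13 Hz on the
system that motivated this work) that is far stronger in phase than in
magnitude, and its reordering sideband can dominate the cardiac band. The
line is detected as the highest periodogram peak in the pump band
(0.08–0.2 Hz, with the respiratory notch `f_R ± 2.5 cpm` excluded once
`f_R` is known) whose power exceeds 3 times the band's upper noise
envelope, taken as the 95th percentile of in-band power with the peak's
immediate neighborhood removed. The upper envelope — rather than, say, the
band median — is the reference because raw periodogram bins are
exponentially distributed: the maximum of ~35 noise bins routinely reaches
5–7 times their median, so a median-referenced threshold with any sensible
factor would fire on pure noise. Absence of the pump is a valid outcome and
simply removes its sidebands from the exclusion list.

## The synthetic generator

`simulateEpi()` produces magnitude + phase series with known ground truth:
an ellipsoidal "brain" (peak baseline 500 a.u., mild radial falloff,
slice-dependent offsets), per-slice cubic drift, quasi-periodic respiratory
and cardiac oscillators, a pump line, Gaussian noise, optional phase
wrapping, and SMS grouping. Design choices:

* **Oscillators.** Instantaneous frequency is `base + AR(1) jitter`
  (coefficient 0.99, innovation SD 5e-4 Hz by default), integrated to
  phase. This gives spectral lines of realistic finite width while keeping
  the run-average frequency within about a tenth of a spectral bin of the
  nominal rate for a 300 s run, so frequency-recovery checks are
  well-posed. Waveform shapes are `sin φ + 0.3 sin 2φ` (cardiac) and
  `sin φ + 0.2 sin 2φ` (respiration), so second harmonics exist for the
  harmonic-band evaluation and the two-harmonic regressors are the correct
  model.
* **Source asymmetry.** Defaults make respiration phase-dominant (0.1 rad
  vs 1.5% of baseline in magnitude) and cardiac magnitude-dominant (3% of
  baseline vs 0.02 rad), mirroring the physics: chest motion perturbs B0
  (phase), pulsatility perturbs spin history and inflow (magnitude).
* **Bulk cardiac pulsatility.** `vesselFraction` defaults to 1: all brain
  voxels carry the cardiac modulation, as brain tissue genuinely pulsates;
  lowering it confines the cardiac signal to a random "vessel" subset.
* **Sideband mechanism.** Additive low-frequency signals alone cannot
  create `k/TR ± f_m` lines after reordering — those require amplitude
  modulation of the TR-periodic carrier. The generator therefore gives the
  phase-borne low-frequency terms a slice-dependent gain
  `1 + m·cos(2π·rank/NS)` (default depth 0.3), which after reordering is
  exactly such a modulated carrier and yields sidebands of amplitude
  `m·a/2`, reproducing the spectra that motivate the exclusion machinery.
* **Noise.** Magnitude noise SD 3 a.u. gives voxel tSNR around 40 once
  physiological noise is included — typical cortical 3 T values; phase
  noise is 0.02 rad.
* **External recordings** are the ground-truth waveforms on a 1/400 s grid
  plus additive noise, mimicking a PMU trace.

What the generator does *not* emulate: motion, ghosting, multi-coil
combination residue, spatially varying physiological delays, heart-rate
variability beyond slow AR(1) drift, and low-frequency respiration-volume
or heart-rate-response effects. Passing tests on this generator therefore
demonstrate the correctness of the signal path and the spectral logic, not
robustness to every artifact of real data.

## Numerical choices and degenerate inputs

* Periodograms are mean-removed and normalized so total power equals the
  series variance; spectrograms use Welch averaging within each 45 s window
  (3 Hann-tapered segments, 50% overlap) stepped by 4 s.
* Voxelwise band power for the evaluation metrics is computed at the volume
  TR; bands above the volume Nyquist are folded to their aliased
  frequencies bin-by-bin before integration. The second-harmonic band
  `2f0 ± halfwidth` is included when its alias is at least one spectral bin
  away from the fundamental band.
* Rank-deficient designs drop dependent columns with a message (all-zero
  regressors therefore leave the data untouched); voxels with zero in-band
  power or zero temporal SD are excluded from the respective averages and
  counted.
* Narrowband edges clipped at Nyquist produce a warning and the clipped
  band is recorded. An exhausted peak search (all in-band power zeroed)
  raises an error suggesting a wider band.
* The per-voxel temporal phase unwrap assumes successive samples differ by
  less than π; it is a fallback for data without spatial unwrapping, and
  leaves any static spatial wrap pattern in place (harmless to a purely
  temporal analysis).

## Known limitations

* A cardiac fundamental lying within a notch of a predicted sideband —
  e.g. exactly at `k/TR ± f_R` — cannot be disambiguated and will be
  zeroed with the sideband. This is intrinsic to the exclusion approach:
  with respiration at 0.25 Hz and TRvol = 2 s, a cardiac rate of exactly
  1.25 Hz collides with `2/TR + f_R`; the aliasing test scenario uses
  respiration at 0.3 Hz for this reason.
* A single fundamental per run is assumed (with ±2.5 cpm / ±6.5 bpm
  spread); strongly bimodal breathing defeats the narrowband step.
* Slice-averaged estimation ignores through-slab physiological delays of
  order 100 ms; at these scales the effect on removal efficacy is small.

## Problem sizes used in the shipped checks

Unit tests run on 16×16 grids with 6–12 slices and 150–450 volumes; the
end-to-end checks use the default conditions (32×32×12, MB = 2, TRvol = 1 s,
NR = 300) with 10–50 seeds per property, chosen to exercise every code path
at comfortable desk scale.
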