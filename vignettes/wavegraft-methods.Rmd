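---
title: "Methods: quantifying early graft-host coupling from calcium-imaging movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying early graft-host coupling from calcium-imaging movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wavegraft)
```

## The measurement problem

When single cardiomyocytes are seeded onto a beating monolayer, the first
hours of electrophysiological integration are visible only as timing
relations in calcium-imaging movies: which stimulated waves elicit a
time-locked transient in the grafted cell, with what delay, and how that
delay compares to the per-contact transit time inside the mature monolayer.
`wavegraft` turns those questions into a reproducible pipeline over
multi-page TIFF movies (e.g. 512x512 px at 34.6 frames/s, field stimulation
at 1 Hz with 20 ms pulses) and single slow confocal raster scans (e.g.
1024x1024 px acquired over 36 s).

All indices are 1-based `(frame, row, col)` with row 1 at the image top;
times in seconds place frame 1 at 0 s. Raw intensities are non-negative
arbitrary units; derived dF/F0 stacks are dimensionless and may be
negative under noise, which the `units` field of `frame_stack()` makes
explicit.

## Denoising chain and SNR

* `subtract_background()` computes per-pixel dF/F0 against a temporal
  percentile baseline (default 10th percentile). The divisor is floored at
  `eps = 1` intensity count: a baseline below one count is
  indistinguishable from zero, and the floor makes the operation idempotent
  once the baseline has been removed.
* `kalman_filter()` is the fixed-gain causal recursion
  `E_t = g E_(t-1) + (1-g) X_t` (default `g = 0.8`), the deterministic core
  of the stack filters used in time-lapse imaging. Its steady-state noise
  variance is `(1-g)/(1+g)` times the input variance, which the tests
  verify by simulation against the closed form. The gain trades noise
  suppression against temporal lag (about `g/(1-g)` frames), so rising-edge
  timing is never measured on Kalman-filtered data in this package.
* `gaussian_blur()` is separable convolution with half-sample symmetric
  (reflective) boundaries, built from banded operator matrices whose
  columns sum to one, so the per-frame mean is conserved exactly.
* `snr_histogram()` is a pixel-count ratio: pixels in a designated signal
  intensity band divided by pixels in the union of noise bands (defaults
  230-280 au versus 150-230 and 280-400 au). A count ratio is the simplest
  statistic consistent with reading signal and noise off an intensity
  histogram; since the published values for this kind of measurement depend
  on the specific recording and denoiser, the package only asserts the
  ordering (filtering increases the ratio), never particular values.
* External denoisers (e.g. a trained neural network) can be slotted in as
  TIFF-to-TIFF transformations between `write_stack()` and `read_stack()`;
  the pipeline treats them as opaque.

## Activation maps and kymographs

`activation_map()` implements a per-pixel *relative* threshold: a pixel
activates when it first exceeds its own temporal mean by `threshold_pct`
percent (default 20). This adapts to heterogeneous resting brightness,
unlike a single absolute threshold. Crossing times are refined by linear
interpolation between the straddling frames, so maps are not quantized to
whole frames; pixels that never cross carry `NA`. The default of 20% is
robust on dF/F-scale transients; the rise-to-threshold latency is a small
constant offset (well under a frame for thresholds up to ~15-20% on the
synthetic transients), which cancels in all relative measurements
(isochrones, velocities, delays).

`reslice_kymograph()` averages a rectangular region across its short axis
to produce a space x time map; off-axis rectangles are sampled bilinearly.
Averaging over `h` rows reduces independent pixel noise about `h`-fold in
variance, which is the main reason kymographs tolerate noise that per-pixel
maps cannot.

`fit_wavefront()` extracts the rising edge per spatial position with the
same relative-threshold rule (the upstroke is the physiologically mapped
event, not the peak) and fits `time = s/v + c` by least squares. With space
vertical and time horizontal, the angle `alpha` between the front line and
the time axis satisfies `v = tan(alpha)` px/frame; descriptions that quote
`1/tan` of the complementary angle (measured against the space axis) are
the same convention. Two degeneracy guards are exposed: a minimum slope
(default 0.02 frames/px, i.e. 50 px/frame) below which the wave is
effectively simultaneous at this frame rate and velocity is reported as
`Inf`, and a maximum RMS residual (default 3 frames) that flags
unreliable fits. When a stimulus train is supplied, one front is fit per
pulse and per-wave speeds are averaged.

## Transmission classification, delay, and the coincidence null

`classify_synchronization()` counts a reference wave as transmitted when a
graft peak falls in `(r, r + window_s]`. The window must be shorter than
the reference spacing, which makes the windows disjoint and the matching
unambiguous. The default window in `transmission_delay()` is 0.8 times the
reference period: wide enough to accept delays of ~10 frames at 34.6
frames/s, narrow enough to exclude the next beat. Fractions are reported
exactly (3 decimals) alongside a whole percentage rounded half-up; counts
round half-up throughout so the conventions are explicit.

`transmission_delay()` matches peaks between an adjacent-monolayer ROI and
the graft ROI. Two deliberate refinements:

* a `lead_s` tolerance (default 2 frames) lets graft peaks slightly
  precede the monolayer peak, because with instant coupling noise jitters
  both peak times and a strict one-sided window would drop half the true
  matches;
* with `robust = TRUE` the summary statistics use the modal delay cluster
  (within `median +/- max(3 MAD, 2 frames)`). A not-yet-fully-coupled
  graft also fires spontaneously, and some spontaneous beats land in the
  matching window by chance with scattered delays; the physiological
  transmission delay is the *consistent* cluster. The full matched list
  and the number excluded are always reported.

`coincidence_probability()` answers "could this much synchronization be
chance?" two ways: an exact binomial tail with per-event hit probability
`p1 = min(1, window x rate)`, and a seeded Monte-Carlo null that draws
jittered periodic spike trains (period `1/rate`, uniform phase, default
jitter 10% of the period) and reruns the matching. The two are
cross-checked against each other in the tests; the Monte-Carlo requires an
explicit seed by contract.

## The cell-chain efficiency model

Wave transit between two monolayer regions is modeled as a chain of `N`
cells in which intercellular contact traversal dominates intracellular
conduction, so the per-contact time is the mean region-to-region peak-time
difference divided by `N`. `N` comes either from direct counting or from
the region distance divided by the average spread cell size (100 um,
rounded half-up, floored at one cell). The graft delay crosses a single
nascent contact, so its per-contact time is the delay itself. The
efficiency ratio of nascent to mature contacts is the ratio of these
per-contact times, with first-order uncertainty propagation. The error
model is: standard error over waves, floored at the frame-quantization
limit `frame_interval / (sqrt(12) N)` (the standard deviation of a
uniform timing error of one frame). This is a reproducible convention,
not a claim about the error model behind any published +/- figures.

## Confocal raster decoding

A slow raster scan of a periodically firing sheet converts time into image
rows: each row is treated as acquired instantaneously at
`line_time = frame_time / height` seconds after the previous one (the
within-row dwell, under one line time, is a documented approximation).
Firing paints horizontal bands, so

* band spacing x line time = firing period (`decode_period()`), e.g.
  21 px x 36 s / 1024 rows = 0.74 s;
* band width x line time = calcium-transient duration
  (`decode_duration()`), e.g. 29 px -> 1.0 s.

`detect_bands()` refines band centers to sub-pixel precision by parabolic
interpolation and reports full widths at half prominence; `refine = FALSE`
reproduces integer-pixel readings taken directly off an image. Decoded
values are reported at full precision alongside the conventional rounding
(period to 2 decimals, duration to 1). `check_commensurability()` tests
whether the frame scan time is an integer multiple of the stimulation
period (relative tolerance on the multiple, default 1%): only then do
bands align vertically across frames and layers; otherwise the pattern is
disordered and cross-layer comparison is not meaningful.

## The synthetic-data generator

`simulate_movie()` produces the statistical structure the analysis
assumes, with a ground-truth manifest for every drawn quantity:

* a planar wave per stimulus, arrival `onset + (c - origin)/v` frames,
  constant across rows;
* calcium transients `A (1 - exp(-t/tau_r)) exp(-t/tau_d)` with defaults
  `tau_r = 50 ms`, `tau_d = 300 ms` — a minimal rise/decay kernel whose
  scale matches a ~1 s transient when widened;
* a graft disk (radius 5 px stands in for the fiber-mounted cell; fiber
  rendering is cosmetic and omitted) that follows each wave with
  probability `p_transmit` after `delay_s`, with a jittered periodic
  pacemaker — not Poisson, matching intrinsic automaticity — that runs
  free between transmitted beats and resets on each one;
* Gaussian read noise, optional Poisson shot noise; every draw derives
  from the single scenario seed, and identical scenarios reproduce the
  TIFF bit-exactly.

The presets encode the study conditions: `"paper-like-graft"` is the
partially integrated (~3 h) state — 1 Hz x 42 stimuli, transmission
probability 0.5, delay 10 frames, a wave crossing the field in 2-3 frames,
and largely suppressed automaticity (spontaneous period 6 s), since at
that stage the cell is described as following roughly every second wave
rather than free-running; `"uncoupled"` is the early (~15 min) state with
a free-running 1.35 s pacemaker; `"perfect-coupling"` and
`"confocal-0.74s"` are the limiting and raster configurations. The
generator deliberately omits curved wavefronts, reaction-diffusion
electrophysiology, motion artifacts, photobleaching and EMCCD gain
statistics, so passing tests demonstrate correctness of the measurement
chain on idealized planar-wave data, not performance on arbitrary real
recordings.

`simulate_raster()` scales the transient kernel so that a band's width at
half prominence in the periodic noiseless profile equals the requested
duration — the operational quantity the decoder measures — rather than the
isolated kernel's width at half maximum, which overlapping decay tails
would bias by ~10%.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly rather than by exception where a
convention exists: constant pixels yield dF/F0 of zero via the `eps`
floor; constant stacks produce all-`NA` activation maps; empty peak or
band sets are legal results; a zero transmitted count fixes the
coincidence probability at one. Ties in peak selection break toward the
earlier peak. Errors are classed conditions (`wavegraft_missing_file`,
`wavegraft_overlapping_windows`, ...) so callers can distinguish failure
modes.

The test suite validates the pipeline at reduced problem sizes chosen to
keep the full run under a minute while preserving the governing ratios
(transient amplitude to noise, delay to frame interval, wave transit to
window): 128x128 px x ~43 s for the graft scenario, 32x128 px for the
efficiency recovery, 1024-row raster frames, and 100000-draw Monte-Carlo
nulls. The efficiency-ratio recovery exercises true ratios of 10 and 40 —
the published-magnitude regime — end to end (activation, peak matching,
delay, cell-chain model) and requires agreement within 15%.

## Known limitations

* Velocity fits assume a planar front aligned with the rectangle's long
  axis; curved or target-wave geometry is out of scope.
* The SNR statistic depends on the chosen intensity bands; it is a
  comparative tool, not an absolute detector metric.
* The cell-chain model collapses conduction into identical serial
  contacts; heterogeneous coupling within the chain is not resolved.
* Raster decoding assumes top-to-bottom unidirectional scanning and a
  sheet firing in unison; z-resolved multi-layer analysis is not
  implemented.
* The coincidence null treats the graft as a jittered periodic oscillator
  independent of the stimulus; entrainment dynamics are not modeled.
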