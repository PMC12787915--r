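# wavegraft

Quantitative analysis of early graft–host electrophysiological integration
from calcium-imaging movies.

When single cardiomyocytes are seeded onto a beating monolayer (for example
stabilized on polymer nanofibers), the first hours of functional coupling
show up only as timing relations in fluorescence recordings: which
stimulated excitation waves elicit a time-locked calcium transient in the
grafted cell, with what delay, and how that delay compares to the
per-contact transit time inside the mature monolayer. `wavegraft` is an R
package for cardiac optical-mapping groups that turns those questions into
a tested, scriptable pipeline:

- **Stack I/O** — multi-page grayscale TIFF movies with a JSON metadata
  sidecar (frame interval, pixel size, provenance/seed); bit-exact
  round-trips for 8/16-bit data.
- **Preprocessing** — per-pixel percentile ΔF/F₀, fixed-gain Kalman stack
  filtering, mass-conserving Gaussian blur, and a histogram-band
  signal-to-noise ratio (pixels in a signal intensity band over pixels in
  noise bands).
- **Wave mapping** — activation maps by a per-pixel *relative* threshold
  (first frame exceeding that pixel's own mean by a set percentage, with
  sub-frame interpolation), reslice kymographs, and conduction velocity
  from the wavefront slope: with space vertical and time horizontal,
  `v = tan(α)` px/frame for the angle α between the front line and the
  time axis.
- **Synchronization & coupling efficiency** — stimulus-locked transmission
  classification (a reference wave at `r` is transmitted iff a graft peak
  lies in `(r, r + w]`), an exact-binomial and a seeded Monte-Carlo
  coincidence null, and the cell-chain model: per-contact time
  `τ = mean(Δt_peak)/N` across an `N`-cell chain, graft per-contact time =
  transmission delay, efficiency ratio `τ_graft/τ_mono` with propagated
  uncertainty.
- **Confocal raster decoding** — in a slow raster scan each image row is a
  time sample (`line_time = frame_time/height`), so band spacing decodes
  the firing period and band width the transient duration.
- **Synthetic data** — seeded generators of stimulus-locked planar-wave
  movies with a graft disk (Bernoulli transmission + jittered pacemaker)
  and of confocal raster frames, each with a ground-truth manifest.

## Worked example

Simulate the partially integrated graft scenario (1 Hz × 42 stimuli at
34.6 frames/s, transmission probability 0.5, programmed delay 10 frames),
then measure the delay, the stimulus-locked fraction, its coincidence
probability, and the contact-efficiency ratio:

```r
library(wavegraft)

sc  <- scenario_presets("paper-like-graft")
sim <- simulate_movie(sc)

td <- transmission_delay(sim$stack,
                         monolayer_roi = disk_roi(64, 88, 3),
                         graft_roi     = sc$graft_roi)
td
#> <transmission_delay> 10.13 +/- 0.63 frames (0.293 +/- 0.018 s) over 23 wave(s)
#>   2 chance-coincidence match(es) excluded from the cluster
td$sync
#> <sync_report> 25 / 42 reference waves transmitted (fraction 0.595, 60%)
#>   matched delays: mean 0.288 s (window 0.809 s)

coincidence_probability(td$sync, graft_rate_hz = 1/6)$p_value
#> [1] 4.27e-12

g <- graft_contact_time(td$delays_s, sc$frame_interval_s)
m <- monolayer_contact_time(c(0.058, 0.060, 0.062), n_cells = 10,
                            frame_interval_s = sc$frame_interval_s)
efficiency_ratio(g, m)
#> <efficiency_estimate> ratio 48.8 +/- 6.9 (monolayer estimator: direct-count)
```

The programmed 10-frame delay is recovered (10.13 ± 0.63 frames ≈ 0.29 s),
the measured fraction 25/42 matches the Bernoulli draw recorded in
`sim$truth`, the binomial tail probability says a pacemaker firing
independently at 1/6 Hz would essentially never match 25 of 42 windows,
and against a 6 ms monolayer per-contact time the nascent contact is ~49×
slower. Decoding a confocal raster frame is pure line-time arithmetic:

```r
fr <- raster_scan_frame(matrix(0, 1024, 1024), frame_time_s = 36)
decode_period(21, fr)
#> $period_s        0.7383  $period_s_rounded   0.74
decode_duration(29, fr)
#> $duration_s      1.0195  $duration_s_rounded 1.0
```

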