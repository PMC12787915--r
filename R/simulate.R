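# Seeded synthetic data: stimulus-locked planar calcium waves over a
# monolayer with a graft disk (Bernoulli transmission + spontaneous
# pacemaking), camera noise, and confocal raster frames of a periodically
# firing sheet. Every run returns a ground-truth manifest.

#' Define a synthetic movie scenario
#'
#' The generative counterpart of a graft-on-monolayer optical-mapping
#' experiment: a planar wave sweeps the field from `wave_origin_col` at
#' `wave_velocity_px_per_frame` after each stimulus; pixels transiently
#' brighten with a rise/decay calcium kernel on top of baseline
#' `baseline_F0`; the graft disk follows each wave with probability
#' `p_transmit` after `delay_s`, otherwise its own jittered pacemaker clock
#' runs free (the clock resets on every transmitted beat); Gaussian read
#' noise and optional Poisson shot noise are added last.
#'
#' @param height_px,width_px Field size in pixels.
#' @param frame_interval_s Seconds per frame.
#' @param n_frames Number of frames.
#' @param wave_velocity_px_per_frame Planar wave speed (> 0, rightward).
#' @param wave_origin_col 1-based column where each wave starts.
#' @param stim A [build_stimulus_train()].
#' @param amplitude Transient amplitude in dF/F0 units.
#' @param tau_rise_s,tau_decay_s Calcium-transient time constants, seconds.
#' @param baseline_F0 Resting fluorescence, arbitrary units.
#' @param graft_roi A [disk_roi()] inside the field, or `NULL` for a plain
#'   monolayer.
#' @param p_transmit Probability a wave is transmitted to the graft.
#' @param delay_s Monolayer-to-graft transmission delay, seconds.
#' @param spont_period_s Spontaneous graft firing period, seconds.
#' @param spont_jitter_s Gaussian jitter of the spontaneous clock, seconds.
#' @param noise_sigma Gaussian read-noise standard deviation, arbitrary
#'   units.
#' @param shot_noise Add Poisson shot noise before read noise.
#' @param pixel_size_um Micrometers per pixel or `NULL`.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `movie_scenario`.
#' @export
movie_scenario <- function(height_px = 128, width_px = 128,
                           frame_interval_s = 1 / 34.6, n_frames = 300,
                           wave_velocity_px_per_frame = 50,
                           wave_origin_col = 1,
                           stim = build_stimulus_train(1.0, 0.02, 8, 0.5),
                           amplitude = 1, tau_rise_s = 0.05,
                           tau_decay_s = 0.3, baseline_F0 = 200,
                           graft_roi = disk_roi(height_px / 2,
                                                round(width_px * 0.75), 5),
                           p_transmit = 0.5, delay_s = 0.29,
                           spont_period_s = 1.35, spont_jitter_s = 0.1,
                           noise_sigma = 20, shot_noise = FALSE,
                           pixel_size_um = NULL, seed = 1L) {
  wg_check(wave_velocity_px_per_frame > 0, "wavegraft_bad_parameter",
           "wave velocity must be positive")
  wg_check(p_transmit >= 0 && p_transmit <= 1, "wavegraft_bad_parameter",
           "p_transmit must lie in [0, 1]")
  wg_check(all(c(tau_rise_s, tau_decay_s, spont_period_s) > 0),
           "wavegraft_bad_parameter", "time constants must be positive")
  wg_check(delay_s >= 0 && spont_jitter_s >= 0 && noise_sigma >= 0,
           "wavegraft_bad_parameter",
           "delay, jitter and noise must be non-negative")
  if (!is.null(graft_roi)) {
    wg_check(inherits(graft_roi, "disk_roi"), "wavegraft_bad_region",
             "graft_roi must be a disk_roi")
    wg_check(graft_roi$center_row - graft_roi$radius_px >= 1 &&
               graft_roi$center_row + graft_roi$radius_px <= height_px &&
               graft_roi$center_col - graft_roi$radius_px >= 1 &&
               graft_roi$center_col + graft_roi$radius_px <= width_px,
             "wavegraft_bad_region", "graft_roi must lie inside the field")
  }
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    frame_interval_s = frame_interval_s, n_frames = as.integer(n_frames),
    wave_velocity_px_per_frame = wave_velocity_px_per_frame,
    wave_origin_col = wave_origin_col, stim = stim,
    amplitude = amplitude, tau_rise_s = tau_rise_s,
    tau_decay_s = tau_decay_s, baseline_F0 = baseline_F0,
    graft_roi = graft_roi, p_transmit = p_transmit, delay_s = delay_s,
    spont_period_s = spont_period_s, spont_jitter_s = spont_jitter_s,
    noise_sigma = noise_sigma, shot_noise = shot_noise,
    pixel_size_um = pixel_size_um, seed = as.integer(seed)
  ), class = "movie_scenario")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Half-prominence band width of the noiseless periodic profile for a given
# kernel time scale, on a fine grid over one period.
periodic_band_width <- function(scale, period_s, n_grid = 4096) {
  tt <- seq(0, period_s, length.out = n_grid)
  f <- numeric(n_grid)
  for (k in -2:2) f <- f + ca_kernel((tt - k * period_s) / scale, 1)
  level <- min(f) + (max(f) - min(f)) / 2
  sum(f >= level) / n_grid * period_s
}

# Kernel time scale such that the periodic profile's half-prominence band
# width equals the requested transient duration.
calibrate_transient_scale <- function(period_s, duration_s) {
  base <- duration_s / ca_kernel_fwhm()
  obj <- function(s) periodic_band_width(s, period_s) - duration_s
  lo <- base * 0.3; hi <- base * 2
  if (obj(lo) * obj(hi) > 0) return(base) # no sign change: fall back
  stats::uniroot(obj, c(lo, hi), tol = 1e-6)$root
}

# Graft firing times: transmitted beats at arrival + delay; between them a
# jittered pacemaker clock runs free and resets on every transmitted beat.
graft_firing_times <- function(arrivals_s, transmitted, delay_s,
                               period_s, jitter_s, duration_s) {
  next_tick <- function(from) {
    from + max(period_s + stats::rnorm(1, 0, jitter_s), period_s / 4)
  }
  spont_next <- stats::runif(1, 0, period_s)
  fired <- numeric(0)
  spont <- numeric(0)
  for (k in seq_along(arrivals_s)) {
    if (!transmitted[k]) next
    f <- arrivals_s[k] + delay_s
    while (spont_next < f) {
      spont <- c(spont, spont_next)
      spont_next <- next_tick(spont_next)
    }
    fired <- c(fired, f)
    spont_next <- next_tick(f)
  }
  while (spont_next < duration_s) {
    spont <- c(spont, spont_next)
    spont_next <- next_tick(spont_next)
  }
  list(transmitted_times = fired, spontaneous_times = spont,
       all_times = sort(c(fired, spont)))
}

#' Simulate a graft-on-monolayer calcium-wave movie
#'
#' Monolayer pixel `(r, c)` fluoresces
#' `F0 * (1 + sum_k K(t - a_k(c)))` with the rise/decay kernel `K` and
#' per-stimulus arrival `a_k(c) = onset_k + (c - origin_col)/v *
#' frame_interval_s` (planar wave, constant across rows). Graft-disk pixels
#' follow the graft firing times instead (see [movie_scenario()]). Frames
#' sample the field instantaneously at `t = (frame - 1) *
#' frame_interval_s`. Identical scenarios and seeds reproduce the stack
#' bit-exactly.
#'
#' @param scenario A [movie_scenario()].
#' @return List with `stack` (a [frame_stack()]) and `truth`, the
#'   ground-truth manifest: `seed`, `stim_onsets_s`,
#'   `arrival_offset_s` (per-column arrival offset added to each onset),
#'   `transmitted` (per-stimulus flags), `graft_fire_times_s`,
#'   `graft_spontaneous_times_s`, `true_velocity_px_per_frame`,
#'   `true_delay_s`, `true_fraction`, `graft_roi`.
#' @export
simulate_movie <- function(scenario) {
  wg_check(inherits(scenario, "movie_scenario"), "wavegraft_bad_parameter",
           "scenario must come from movie_scenario()")
  sc <- scenario
  with_seed(sc$seed, {
    dt <- sc$frame_interval_s
    t_s <- (seq_len(sc$n_frames) - 1) * dt
    duration <- sc$n_frames * dt
    cols <- seq_len(sc$width_px)
    offset <- (cols - sc$wave_origin_col) / sc$wave_velocity_px_per_frame * dt
    onsets <- sc$stim$onset_times_s
    # monolayer dF/F depends only on (frame, column)
    dff <- matrix(0, sc$n_frames, sc$width_px)
    for (on in onsets) {
      tt <- outer(t_s, on + offset, "-")
      dff <- dff + matrix(
        ca_kernel(as.vector(tt), sc$amplitude, sc$tau_rise_s, sc$tau_decay_s),
        sc$n_frames, sc$width_px)
    }
    mono <- sc$baseline_F0 * (1 + dff)
    frames <- array(0, c(sc$n_frames, sc$height_px, sc$width_px))
    for (r in seq_len(sc$height_px)) frames[, r, ] <- mono
    truth <- list(seed = sc$seed, stim_onsets_s = onsets,
                  arrival_offset_s = offset,
                  true_velocity_px_per_frame = sc$wave_velocity_px_per_frame,
                  true_delay_s = sc$delay_s,
                  graft_roi = sc$graft_roi)
    if (!is.null(sc$graft_roi)) {
      transmitted <- stats::runif(length(onsets)) < sc$p_transmit
      arrivals <- onsets + offset[round(sc$graft_roi$center_col)]
      ev <- graft_firing_times(arrivals, transmitted, sc$delay_s,
                               sc$spont_period_s, sc$spont_jitter_s, duration)
      gdff <- if (length(ev$all_times)) {
        rowSums(vapply(ev$all_times, function(f)
          ca_kernel(t_s - f, sc$amplitude, sc$tau_rise_s, sc$tau_decay_s),
          numeric(sc$n_frames)))
      } else numeric(sc$n_frames)
      gvals <- sc$baseline_F0 * (1 + gdff)
      mask <- roi_mask(sc$graft_roi, sc$height_px, sc$width_px)
      idx <- which(mask)
      flat <- matrix(frames, nrow = sc$n_frames)
      flat[, idx] <- gvals
      frames <- array(flat, dim(frames))
      truth$transmitted <- transmitted
      truth$graft_fire_times_s <- ev$transmitted_times
      truth$graft_spontaneous_times_s <- ev$spontaneous_times
      truth$true_fraction <- mean(transmitted)
    }
    if (sc$shot_noise)
      frames <- array(stats::rpois(length(frames), pmax(frames, 0)),
                      dim(frames))
    if (sc$noise_sigma > 0)
      frames <- frames + stats::rnorm(length(frames), 0, sc$noise_sigma)
    frames <- pmax(frames, 0)
    list(stack = frame_stack(frames, dt, sc$pixel_size_um, units = "au",
                             seed = sc$seed),
         truth = truth)
  })
}

#' Simulate a confocal raster-scan frame of a firing sheet
#'
#' The whole sheet fires periodically; scan row `l` (1-based, top to
#' bottom) records the sheet fluorescence at `phase_s + (l - 1) *
#' frame_time_s / height_px`, so each firing paints a bright band and bands
#' repeat every `sheet_period_s * height_px / frame_time_s` rows. The
#' transient uses the same rise/decay kernel as [simulate_movie()], time
#' scaled so that a band's full width at half prominence in the periodic
#' noiseless profile equals `transient_duration_s` — the operational width
#' the band decoder measures (with overlapping decay tails this differs
#' slightly from the isolated kernel's width at half maximum).
#'
#' @param sheet_period_s Sheet firing period, seconds (> 0).
#' @param transient_duration_s Transient full width at half maximum,
#'   seconds (< `sheet_period_s`).
#' @param height_px,width_px Frame geometry; default 1024 x 128.
#' @param frame_time_s Seconds per full frame; default 36.
#' @param phase_s Sheet clock offset at the scan start, seconds.
#' @param amplitude Transient amplitude relative to baseline 1.
#' @param noise_sigma Gaussian noise standard deviation (same units).
#' @param seed Integer seed.
#' @return List with `frame` (a [raster_scan_frame()]) and `truth`:
#'   `band_spacing_rows`, `band_width_rows`, `period_s`, `duration_s`,
#'   `firing_times_s`, `seed`.
#' @export
simulate_raster <- function(sheet_period_s, transient_duration_s,
                            height_px = 1024, width_px = 128,
                            frame_time_s = 36, phase_s = 0,
                            amplitude = 1, noise_sigma = 0.05, seed = 1L) {
  wg_check(sheet_period_s > 0, "wavegraft_bad_parameter",
           "sheet_period_s must be positive")
  wg_check(transient_duration_s > 0 && transient_duration_s < sheet_period_s,
           "wavegraft_bad_parameter",
           "transient_duration_s must lie in (0, sheet_period_s)")
  with_seed(seed, {
    lt <- frame_time_s / height_px
    row_t <- phase_s + (seq_len(height_px) - 1) * lt
    scale <- calibrate_transient_scale(sheet_period_s, transient_duration_s)
    first <- floor(min(row_t) / sheet_period_s) - 1
    last <- ceiling(max(row_t) / sheet_period_s) + 1
    fires <- (first:last) * sheet_period_s
    prof <- rep(1, height_px)
    for (f in fires)
      prof <- prof + ca_kernel((row_t - f) / scale, amplitude)
    img <- matrix(prof, height_px, width_px)
    if (noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, noise_sigma)
    img <- pmax(img, 0)
    list(frame = raster_scan_frame(img, frame_time_s),
         truth = list(band_spacing_rows = sheet_period_s * height_px /
                        frame_time_s,
                      band_width_rows = transient_duration_s * height_px /
                        frame_time_s,
                      period_s = sheet_period_s,
                      duration_s = transient_duration_s,
                      firing_times_s = fires, seed = seed))
  })
}

#' Named scenario presets
#'
#' Ready-made study conditions:
#' * `"paper-like-graft"` — the partially integrated (~3 h) state:
#'   128 x 128 px at 34.6 frames/s, 1 Hz x 42 stimuli, fast wave
#'   (50 px/frame, the field crossed in 2-3 frames), transmission
#'   probability 0.5, delay 10 frames, read noise 20 au. Intrinsic
#'   automaticity is largely suppressed at this stage (spontaneous period
#'   6 s), so spontaneous beats appear only during long non-transmitted
#'   runs.
#' * `"perfect-coupling"` — every wave transmitted with zero delay, no
#'   noise.
#' * `"uncoupled"` — no transmission; the graft free-runs on its pacemaker.
#' * `"confocal-0.74s"` — raster configuration: a sheet firing every
#'   0.74 s scanned at 1024 rows / 36 s (bands every ~21 rows).
#'
#' @param name Preset name; `NULL` lists all presets as a named list.
#' @return A `movie_scenario`, a raster configuration list (for
#'   `"confocal-0.74s"`), or a named list of all presets.
#' @export
scenario_presets <- function(name = NULL) {
  dt <- 1 / 34.6
  presets <- list(
    "paper-like-graft" = movie_scenario(
      height_px = 128, width_px = 128, frame_interval_s = dt,
      n_frames = ceiling(43.5 / dt),
      wave_velocity_px_per_frame = 50, wave_origin_col = 1,
      stim = build_stimulus_train(1.0, 0.02, 42, 0.5, 5),
      amplitude = 1, baseline_F0 = 200,
      graft_roi = disk_roi(64, 96, 5),
      p_transmit = 0.5, delay_s = 10 * dt,
      spont_period_s = 6, spont_jitter_s = 0.25,
      noise_sigma = 20, seed = 7L),
    "perfect-coupling" = movie_scenario(
      height_px = 64, width_px = 64, frame_interval_s = dt,
      n_frames = ceiling(13.5 / dt),
      wave_velocity_px_per_frame = 50, wave_origin_col = 1,
      stim = build_stimulus_train(1.0, 0.02, 12, 0.5, 5),
      amplitude = 1, baseline_F0 = 200,
      graft_roi = disk_roi(32, 48, 5),
      p_transmit = 1, delay_s = 0, spont_period_s = 1.35,
      spont_jitter_s = 0.1, noise_sigma = 0, seed = 7L),
    "uncoupled" = movie_scenario(
      height_px = 64, width_px = 64, frame_interval_s = dt,
      n_frames = ceiling(43.5 / dt),
      wave_velocity_px_per_frame = 50, wave_origin_col = 1,
      stim = build_stimulus_train(1.0, 0.02, 42, 0.5, 5),
      amplitude = 1, baseline_F0 = 200,
      graft_roi = disk_roi(32, 48, 5),
      p_transmit = 0, delay_s = 10 * dt, spont_period_s = 1.35,
      spont_jitter_s = 0.1, noise_sigma = 10, seed = 7L),
    "confocal-0.74s" = list(
      type = "raster", sheet_period_s = 0.74, transient_duration_s = 0.30,
      height_px = 1024, width_px = 128, frame_time_s = 36,
      phase_s = 0.2, amplitude = 1, noise_sigma = 0.05, seed = 7L)
  )
  if (is.null(name)) return(presets)
  wg_check(name %in% names(presets), "wavegraft_unknown_preset",
           sprintf("unknown preset '%s'", name))
  presets[[name]]
}

#' Write a movie scenario to YAML
#'
#' @param scenario A [movie_scenario()].
#' @param path Destination YAML file.
#' @return `path`, invisibly.
#' @export
scenario_to_yaml <- function(scenario, path) {
  wg_check(inherits(scenario, "movie_scenario"), "wavegraft_bad_parameter",
           "scenario must come from movie_scenario()")
  x <- unclass(scenario)
  x$stim <- unclass(x$stim)
  x$graft_roi <- if (is.null(x$graft_roi)) NULL else unclass(x$graft_roi)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a movie scenario from YAML
#'
#' @param path YAML file written by [scenario_to_yaml()] (or hand-edited
#'   with the same fields).
#' @return A [movie_scenario()].
#' @export
scenario_from_yaml <- function(path) {
  wg_check(file.exists(path), "wavegraft_missing_file",
           sprintf("no such file: '%s'", path))
  x <- yaml::read_yaml(path)
  stim <- x$stim
  movie_scenario(
    height_px = x$height_px, width_px = x$width_px,
    frame_interval_s = x$frame_interval_s, n_frames = x$n_frames,
    wave_velocity_px_per_frame = x$wave_velocity_px_per_frame,
    wave_origin_col = x$wave_origin_col,
    stim = build_stimulus_train(stim$period_s, stim$pulse_duration_s,
                                length(stim$onset_times_s),
                                stim$onset_times_s[1],
                                stim$amplitude_V %||% NA_real_),
    amplitude = x$amplitude, tau_rise_s = x$tau_rise_s,
    tau_decay_s = x$tau_decay_s, baseline_F0 = x$baseline_F0,
    graft_roi = if (is.null(x$graft_roi)) NULL else
      disk_roi(x$graft_roi$center_row, x$graft_roi$center_col,
               x$graft_roi$radius_px),
    p_transmit = x$p_transmit, delay_s = x$delay_s,
    spont_period_s = x$spont_period_s, spont_jitter_s = x$spont_jitter_s,
    noise_sigma = x$noise_sigma, shot_noise = isTRUE(x$shot_noise),
    pixel_size_um = x$pixel_size_um, seed = x$seed)
}
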