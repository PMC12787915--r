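# Synthetic generator: determinism, physical limits, conservation, presets.

test_that("identical scenario and seed reproduce the movie bit-exactly", {
  sc <- movie_scenario(height_px = 24, width_px = 24, n_frames = 60,
                       graft_roi = disk_roi(12, 18, 3), noise_sigma = 10,
                       shot_noise = TRUE, seed = 40)
  a <- simulate_movie(sc)
  b <- simulate_movie(sc)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  sc2 <- sc; sc2$seed <- 41L
  expect_false(identical(simulate_movie(sc2)$stack$frames, a$stack$frames))
})

test_that("with perfect instant coupling the graft trace equals the monolayer underneath", {
  sc <- scenario_presets("perfect-coupling")
  sc$spont_period_s <- 1e6 # pacemaker quiescent: transmission only
  sim <- simulate_movie(sc)
  graft <- roi_trace(sim$stack, sc$graft_roi)
  under <- wg_trace(sim$stack$frames[, 10, sc$graft_roi$center_col],
                    sim$stack$frame_interval_s)
  expect_equal(graft$values, under$values, tolerance = 1e-12)
  expect_equal(sim$truth$true_fraction, 1)
})

test_that("the perfect-coupling preset transmits every wave", {
  sim <- simulate_movie(scenario_presets("perfect-coupling"))
  expect_equal(sim$truth$true_fraction, 1)
  expect_length(sim$truth$graft_fire_times_s, 12)
})

test_that("noiseless time-mean fluorescence matches the analytic kernel mean", {
  dt <- 1 / 34.6
  sc <- movie_scenario(height_px = 4, width_px = 8, frame_interval_s = dt,
                       n_frames = ceiling(40 / dt),
                       wave_velocity_px_per_frame = 50,
                       stim = build_stimulus_train(1, 0.02, 30, 2),
                       amplitude = 1, baseline_F0 = 200, graft_roi = NULL,
                       noise_sigma = 0, seed = 42)
  sim <- simulate_movie(sc)
  # independent dense-grid integral of the transient kernel
  tt <- seq(0, 5, by = 1e-4)
  kint <- sum((1 - exp(-tt / 0.05)) * exp(-tt / 0.3)) * 1e-4
  expected <- 200 * (1 + 30 * kint / 40)
  got <- mean(sim$stack$frames[, 2, 4])
  expect_lt(abs(got - expected) / expected, 0.01)
})

test_that("velocity-recovery error degrades monotonically with noise", {
  dt <- 1 / 34.6
  err_at <- function(sigma) {
    errs <- vapply(1:5, function(s) {
      sc <- movie_scenario(height_px = 16, width_px = 64,
                           frame_interval_s = dt, n_frames = 160,
                           wave_velocity_px_per_frame = 2, wave_origin_col = 1,
                           stim = build_stimulus_train(4, 0.02, 1, 0.3),
                           amplitude = 1, baseline_F0 = 200, graft_roi = NULL,
                           noise_sigma = sigma, seed = s)
      sim <- simulate_movie(sc)
      k <- reslice_kymograph(gaussian_blur(sim$stack, 1.5),
                             rect_region(4, 1, 8, 64))
      f <- fit_wavefront(k)
      if (f$degenerate) 10 else abs(f$slope_px_per_frame - 2) / 2
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(0), err_at(100), err_at(200))
  expect_true(all(diff(e) >= -1e-12))
})

test_that("uncoupled graft firing is consistent with the binomial coincidence null", {
  sc <- scenario_presets("uncoupled")
  sim <- simulate_movie(sc)
  expect_equal(sim$truth$true_fraction, 0)
  rep <- classify_synchronization(sc$stim,
                                  sim$truth$graft_spontaneous_times_s, 0.8)
  ct <- coincidence_probability(rep, 1 / sc$spont_period_s)
  # an independent pacemaker should not look significantly synchronized
  expect_gt(ct$p_value, 0.01)
})

test_that("raster band geometry follows the scan arithmetic", {
  rs <- simulate_raster(0.74, 0.3, height_px = 1024, width_px = 16,
                        frame_time_s = 36, seed = 43)
  expect_equal(rs$truth$band_spacing_rows, 0.74 * 1024 / 36)
  b <- detect_bands(side_projection(rs$frame))
  expect_lt(max(abs(diff(b$band_centers_px) - 21.05)), 1)
  # period equal to the frame time paints exactly one band
  one <- simulate_raster(36, 3, height_px = 256, width_px = 8,
                         frame_time_s = 36, phase_s = 18, noise_sigma = 0.01,
                         seed = 44)
  expect_length(detect_bands(side_projection(one$frame))$band_centers_px, 1)
})

test_that("scenarios round-trip through YAML and presets are validated", {
  sc <- scenario_presets("paper-like-graft")
  path <- withr::local_tempfile(fileext = ".yaml")
  scenario_to_yaml(sc, path)
  back <- scenario_from_yaml(path)
  expect_equal(back$stim$onset_times_s, sc$stim$onset_times_s)
  back$stim <- sc$stim # remaining fields compared wholesale
  expect_equal(unclass(back)[order(names(back))],
               unclass(sc)[order(names(sc))], tolerance = 1e-12)
  expect_named(scenario_presets(), c("paper-like-graft", "perfect-coupling",
                                     "uncoupled", "confocal-0.74s"))
  expect_error(scenario_presets("nope"), class = "wavegraft_unknown_preset")
})
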