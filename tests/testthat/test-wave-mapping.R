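# Activation maps, kymographs, wavefront fits, transmission delay.

test_that("activation_map matches the brute-force per-pixel oracle", {
  withr::local_seed(10)
  for (i in 1:8) {
    stk <- random_stack(30, 8, 8)
    win <- sort(sample(1:30, 2))
    if (diff(win) < 3) win <- c(1, 30)
    m <- activation_map(stk, threshold_pct = 15, window = win)
    expect_equal(m$time_frames,
                 oracle_activation_map(stk$frames, 15, win),
                 tolerance = 1e-9)
  }
})

test_that("a constant stack never activates", {
  stk <- frame_stack(array(5, c(20, 6, 6)), 0.1)
  expect_true(all(is.na(activation_map(stk)$time_frames)))
})

test_that("activation times track the true planar-wave arrival and order the field", {
  sc <- movie_scenario(height_px = 16, width_px = 96, frame_interval_s = 1 / 34.6,
                       n_frames = 120, wave_velocity_px_per_frame = 2,
                       wave_origin_col = 1,
                       stim = build_stimulus_train(3, 0.02, 1, 0.3),
                       amplitude = 1, baseline_F0 = 200, graft_roi = NULL,
                       noise_sigma = 41, seed = 11) # transient peak / sigma ~ 3
  sim <- simulate_movie(sc)
  # a 12% rise criterion keeps the rise-to-threshold latency sub-frame
  m <- activation_map(gaussian_blur(sim$stack, 1.5), 12)
  # true arrival in frames (frame 1 = 0 s)
  a_true <- outer(rep(1, 16), 0.3 + sim$truth$arrival_offset_s) /
    sc$frame_interval_s + 1
  err <- abs(m$time_frames - a_true)[, 5:92] # clear of blur boundary columns
  expect_gt(mean(err <= 1, na.rm = TRUE), 0.99)
  # upstream activates before downstream
  expect_lt(mean(m$time_frames[, 1:10]), mean(m$time_frames[, 80:96]))
})

test_that("the graft region activates after the adjacent monolayer", {
  sc <- scenario_presets("perfect-coupling")
  sc$delay_s <- 0.2
  sim <- simulate_movie(sc)
  m <- activation_map(sim$stack, 20, window = c(1, 45))
  g <- roi_mask(sc$graft_roi, 64, 64)
  expect_gt(mean(m$time_frames[g], na.rm = TRUE),
            mean(m$time_frames[!g], na.rm = TRUE))
})

test_that("reslice of a height-1 region is the raw line and averaging reduces noise", {
  withr::local_seed(12)
  stk <- random_stack(25, 20, 30)
  k1 <- reslice_kymograph(stk, rect_region(7, 3, 1, 20))
  expect_equal(k1$intensity, t(stk$frames[, 7, 3:22]))
  # variance of the mean across an h-row region drops ~h-fold
  h <- 16
  noise <- frame_stack(array(rnorm(40 * 20 * 30, 100, 10), c(40, 20, 30)), 0.1)
  kh <- reslice_kymograph(noise, rect_region(1, 1, h, 30))
  ratio <- var(as.numeric(noise$frames)) / var(as.numeric(kh$intensity))
  expect_lt(abs(ratio - h) / h, 0.2)
})

test_that("reslice averaging is linear: region total per frame is preserved", {
  withr::local_seed(13)
  stk <- random_stack(15, 12, 18)
  region <- rect_region(2, 3, 6, 10)
  k <- reslice_kymograph(stk, region)
  for (t in c(1, 8, 15)) {
    direct <- sum(stk$frames[t, 2:7, 3:12])
    expect_lt(abs(colSums(k$intensity)[t] * 6 - direct) / direct, 1e-6)
  }
  expect_error(reslice_kymograph(stk, rect_region(10, 10, 6, 10)),
               class = "wavegraft_bad_region")
})

test_that("an oblique region is resliced along its rotated long axis", {
  # gradient along rows only: a 90-degree region reads the row gradient
  fr <- array(0, c(3, 40, 40))
  for (t in 1:3) fr[t, , ] <- matrix(seq_len(40), 40, 40)
  stk <- frame_stack(fr, 0.1)
  k <- reslice_kymograph(stk, rect_region(5, 20, 1, 30, orientation_deg = 90))
  expect_equal(k$intensity[, 1], 5:34, tolerance = 1e-9)
})

test_that("fit_wavefront recovers programmed velocities within 10%", {
  dt <- 1 / 34.6
  for (v in c(1, 2, 4)) {
    sc <- movie_scenario(height_px = 24, width_px = 96, frame_interval_s = dt,
                         n_frames = ceiling(16 / dt),
                         wave_velocity_px_per_frame = v, wave_origin_col = 1,
                         stim = build_stimulus_train(5, 0.02, 3, 0.5),
                         amplitude = 1, baseline_F0 = 200, graft_roi = NULL,
                         noise_sigma = 200 / 3, seed = 14)
    sim <- simulate_movie(sc)
    k <- reslice_kymograph(gaussian_blur(sim$stack, 1.5),
                           rect_region(8, 1, 10, 96))
    f <- fit_wavefront(k, sc$stim)
    expect_false(f$degenerate)
    expect_lt(abs(f$slope_px_per_frame - v) / v, 0.1)
    expect_equal(f$alpha_deg, atan(f$slope_px_per_frame) * 180 / pi)
  }
})

test_that("a simultaneous wave is flagged degenerate with unbounded velocity", {
  # every position brightens on the same frames: slope ~ 0 along space
  K <- matrix(1, 40, 60)
  K[, c(20, 40)] <- 60
  kym <- structure(list(intensity = K, frame_interval_s = 0.03,
                        pixel_size_um = NULL,
                        source_region = rect_region(1, 1, 1, 40)),
                   class = "kymograph")
  f <- fit_wavefront(kym)
  expect_true(f$degenerate)
  expect_identical(f$slope_px_per_frame, Inf)
})

test_that("wavefront speed is invariant to reversing the space axis", {
  dt <- 1 / 34.6
  sc <- movie_scenario(height_px = 16, width_px = 64, frame_interval_s = dt,
                       n_frames = 150, wave_velocity_px_per_frame = 2,
                       wave_origin_col = 1,
                       stim = build_stimulus_train(4, 0.02, 1, 0.3),
                       amplitude = 1, baseline_F0 = 200, graft_roi = NULL,
                       noise_sigma = 30, seed = 15)
  sim <- simulate_movie(sc)
  k <- reslice_kymograph(sim$stack, rect_region(4, 1, 8, 64))
  kr <- k
  kr$intensity <- k$intensity[nrow(k$intensity):1, ]
  expect_equal(fit_wavefront(kr)$slope_px_per_frame,
               fit_wavefront(k)$slope_px_per_frame, tolerance = 1e-9)
})

test_that("transmission_delay recovers programmed delays including instant coupling", {
  dt <- 1 / 34.6
  for (delay_frames in c(0, 10)) {
    sc <- movie_scenario(height_px = 48, width_px = 64, frame_interval_s = dt,
                         n_frames = ceiling(13 / dt),
                         wave_velocity_px_per_frame = 50, wave_origin_col = 1,
                         stim = build_stimulus_train(1, 0.02, 12, 0.5),
                         amplitude = 1, baseline_F0 = 200,
                         graft_roi = disk_roi(32, 48, 5), p_transmit = 1,
                         delay_s = delay_frames * dt, spont_period_s = 1e6,
                         noise_sigma = 15, seed = 16)
    sim <- simulate_movie(sc)
    td <- transmission_delay(sim$stack, disk_roi(10, 48, 3), sc$graft_roi)
    expect_lt(abs(td$mean_frames - delay_frames), 1)
    # unit conversion is exact
    expect_equal(td$mean_s, td$mean_frames * dt)
  }
})

test_that("transmission_delay raises when nothing is transmitted", {
  dt <- 1 / 34.6
  sc <- movie_scenario(height_px = 32, width_px = 48, frame_interval_s = dt,
                       n_frames = ceiling(6 / dt),
                       wave_velocity_px_per_frame = 50,
                       stim = build_stimulus_train(1, 0.02, 5, 0.5),
                       graft_roi = disk_roi(16, 36, 4), p_transmit = 0,
                       spont_period_s = 1e6, noise_sigma = 0, seed = 17)
  sim <- simulate_movie(sc)
  expect_error(transmission_delay(sim$stack, disk_roi(6, 36, 3), sc$graft_roi),
               class = "wavegraft_error")
})
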