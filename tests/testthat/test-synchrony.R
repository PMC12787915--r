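# Peak detection, stimulus-locked classification, coincidence null, and the
# cell-chain efficiency model.

test_that("detect_peaks matches the brute-force prominence oracle", {
  withr::local_seed(20)
  for (i in 1:20) {
    v <- cumsum(rnorm(200))
    tr <- wg_trace(v - min(v), 0.05)
    got <- detect_peaks(tr, min_prominence = 0.1)
    want <- oracle_peaks(tr$values, 0.1)
    expect_equal(got$indices, want$indices)
    expect_equal(got$prominences,
                 want$prominences / diff(range(tr$values)))
  }
})

test_that("detect_peaks finds a clean 1 Hz transient train and nothing on monotone traces", {
  dt <- 1 / 34.6
  v <- transient_trace(ceiling(43 / dt), dt, 0:41 + 0.3)
  pk <- detect_peaks(wg_trace(v, dt), 0.2, 0.5)
  expect_length(pk$peak_times_s, 42)
  expect_lt(max(abs(diff(pk$peak_times_s) - 1)), dt + 1e-9)
  expect_length(detect_peaks(wg_trace(seq_len(50), 0.1))$indices, 0)
})

test_that("minimum separation keeps the more prominent peak, earlier on ties", {
  v <- c(0, 1, 0, 0.8, 0, 0, 2, 0, 2, 0)
  tr <- wg_trace(v, 1)
  pk <- detect_peaks(tr, 0.1, min_separation_s = 3)
  # the two ties at 2 are 2 s apart: earlier one (index 7) wins;
  # index 2 (prom 1) beats index 4 within its 3 s neighborhood
  expect_equal(pk$indices, c(2, 7))
})

test_that("classification reproduces the every-second-wave regime and edge cases", {
  ref <- 0:41
  graft <- seq(0, 40, by = 2) + 0.3
  rep1 <- classify_synchronization(ref, graft, 0.8)
  expect_equal(rep1$n_transmitted, 21)
  expect_equal(rep1$fraction, 0.5)
  expect_equal(rep1$delays_s, rep(0.3, 21))
  # empty graft series
  rep0 <- classify_synchronization(ref, numeric(0), 0.8)
  expect_equal(rep0$fraction, 0)
  expect_equal(rep0$coincidence_p, 1)
  # overlapping windows are rejected
  expect_error(classify_synchronization(ref, graft, 1.0),
               class = "wavegraft_overlapping_windows")
})

test_that("the transmission fraction is invariant to a common time shift", {
  withr::local_seed(21)
  ref <- cumsum(runif(30, 1, 1.4))
  graft <- sort(runif(25, 0, max(ref)))
  a <- classify_synchronization(ref, graft, 0.5)
  b <- classify_synchronization(ref + 13.7, graft + 13.7, 0.5)
  expect_equal(a$fraction, b$fraction)
  expect_equal(a$delays_s, b$delays_s)
})

test_that("Bernoulli transmission at p = 0.5 lands in the exact binomial interval", {
  withr::local_seed(22)
  ref <- 0:41
  transmitted <- runif(42) < 0.5
  graft <- ref[transmitted] + 0.3
  rep <- classify_synchronization(ref, graft, 0.8)
  ci <- qbinom(c(0.025, 0.975), 42, 0.5)
  expect_gte(rep$n_transmitted, ci[1])
  expect_lte(rep$n_transmitted, ci[2])
})

test_that("coincidence probability: closed form, trivial cases and monotonicity", {
  ref <- 0:41
  mk <- function(n_trans) {
    classify_synchronization(ref, ref[seq_len(n_trans)] + 0.2, 0.3)
  }
  # zero transmissions -> probability 1 under any null
  expect_equal(coincidence_probability(mk(0), 0.5)$p_value, 1)
  # closed form is the exact binomial tail
  ct <- coincidence_probability(mk(20), 0.5)
  expect_equal(ct$p1, 0.15)
  expect_equal(ct$p_value, pbinom(19, 42, 0.15, lower.tail = FALSE))
  # monotonically decreasing in the transmitted count
  ps <- sapply(c(5, 10, 20, 30), function(n)
    coincidence_probability(mk(n), 0.5)$p_value)
  expect_true(all(diff(ps) < 0))
  # reproducibility contract: monte-carlo without a seed is refused
  expect_error(coincidence_probability(mk(20), 0.5, "monte-carlo"),
               class = "wavegraft_seed_required")
})

test_that("a graft copying every reference event gives fraction 1 and the point null", {
  ref <- 0:29
  rep <- classify_synchronization(ref, ref + 0.2, 0.4)
  expect_equal(rep$fraction, 1)
  ct <- coincidence_probability(rep, 1)
  expect_equal(ct$p_value, (0.4)^30)
})

test_that("cells_from_distance rounds half-up with a floor of one cell", {
  expect_equal(cells_from_distance(1000, 100), 10)
  expect_equal(cells_from_distance(100, 100), 1)
  expect_equal(cells_from_distance(149, 100), 1)
  expect_equal(cells_from_distance(150, 100), 2)
  expect_equal(cells_from_distance(20, 100), 1)
  expect_error(cells_from_distance(-5, 100), class = "wavegraft_bad_parameter")
})

test_that("contact times follow the cell-chain arithmetic and scale linearly", {
  ct <- monolayer_contact_time(0.06, n_cells = 10)
  expect_equal(ct$value_s, 0.006)
  expect_equal(monolayer_contact_time(c(0.5, 0.7), 1)$value_s, 0.6)
  a <- monolayer_contact_time(c(0.05, 0.06, 0.07), 10)
  b <- monolayer_contact_time(2 * c(0.05, 0.06, 0.07), 10)
  expect_equal(b$value_s, 2 * a$value_s)
  expect_equal(b$sigma_s, 2 * a$sigma_s)
  # frame-quantization floor applies when the spread is tiny
  fl <- monolayer_contact_time(rep(0.06, 5), 10, frame_interval_s = 1 / 34.6)
  expect_equal(fl$sigma_s, (1 / 34.6) / (sqrt(12) * 10))
  expect_error(monolayer_contact_time(numeric(0), 10),
               class = "wavegraft_bad_parameter")
})

test_that("efficiency ratios propagate uncertainty and invert reciprocally", {
  g <- structure(list(value_s = 0.264, sigma_s = 0.264 * 0.2,
                      method = "graft"), class = "contact_time")
  m <- structure(list(value_s = 0.006, sigma_s = 0.006 * 0.2,
                      method = "direct-count"), class = "contact_time")
  eff <- efficiency_ratio(g, m)
  expect_equal(eff$ratio, 44)
  expect_equal(eff$sigma, 44 * sqrt(2 * 0.2^2))
  expect_equal(efficiency_ratio(g, g)$ratio, 1)
  expect_lt(abs(efficiency_ratio(g, m)$ratio *
                  efficiency_ratio(m, g)$ratio - 1), 1e-9)
})
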