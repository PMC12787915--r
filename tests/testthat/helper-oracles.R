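# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive explicit loops, independent of the package's
# vectorized implementations.

# Activation map by explicit per-pixel, per-frame scan with the same
# relative-threshold + linear-interpolation rule.
oracle_activation_map <- function(frames, threshold_pct, window) {
  idx <- window[1]:window[2]
  H <- dim(frames)[2]; W <- dim(frames)[3]
  out <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    x <- frames[idx, r, c]
    thr <- (1 + threshold_pct / 100) * mean(x)
    for (t in seq_along(x)) {
      if (x[t] >= thr) {
        out[r, c] <- if (t == 1) 1 else
          (t - 1) + (thr - x[t - 1]) / (x[t] - x[t - 1])
        break
      }
    }
  }
  out + (window[1] - 1)
}

# All local maxima with prominences by O(n^2) scan: for each strict local
# max, walk each side to the nearest strictly higher sample, track the
# minimum, prominence = height - max(side minima).
oracle_peaks <- function(v, min_prom_frac) {
  n <- length(v)
  peaks <- integer(0); proms <- numeric(0)
  for (i in 2:(n - 1)) {
    if (!(v[i] > v[i - 1] && v[i] > v[i + 1])) next
    lmin <- v[i]
    for (j in (i - 1):1) {
      if (v[j] > v[i]) break
      lmin <- min(lmin, v[j])
    }
    rmin <- v[i]
    for (j in (i + 1):n) {
      if (v[j] > v[i]) break
      rmin <- min(rmin, v[j])
    }
    peaks <- c(peaks, i)
    proms <- c(proms, v[i] - max(lmin, rmin))
  }
  keep <- proms >= min_prom_frac * diff(range(v))
  list(indices = peaks[keep], prominences = proms[keep])
}

# A noiseless baseline+transient pixel trace.
transient_trace <- function(n, dt, events_s, baseline = 100, amp = 1,
                            tau_r = 0.05, tau_d = 0.3) {
  t_s <- (seq_len(n) - 1) * dt
  v <- rep(baseline, n)
  for (f in events_s) {
    u <- t_s - f
    v <- v + baseline * amp * ifelse(u >= 0,
                                     (1 - exp(-u / tau_r)) * exp(-u / tau_d),
                                     0)
  }
  v
}

# Small random stack with positive intensities.
random_stack <- function(n = 30, h = 8, w = 8, dt = 0.1) {
  frame_stack(array(runif(n * h * w, 0, 100), c(n, h, w)), dt)
}
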