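# Internal helpers: structured errors, rounding, kernels, bilinear sampling.

# Structured condition so callers can distinguish failure modes by class.
wg_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "wavegraft_error"),
                      call = call))
}

wg_check <- function(ok, class, msg) {
  if (!isTRUE(ok)) wg_stop(class, msg, call = sys.call(-1))
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Round half up (counts and reported percentages; R's round() is half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Calcium-transient kernel: difference-of-exponentials rise/decay, 0 for t < 0.
ca_kernel <- function(t, amplitude = 1, tau_rise_s = 0.05, tau_decay_s = 0.3) {
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  out[pos] <- amplitude * (1 - exp(-tp / tau_rise_s)) * exp(-tp / tau_decay_s)
  out
}

# Full width at half maximum of the unit ca_kernel with given time constants,
# found on a fine grid (used to scale raster transients to a stated duration).
ca_kernel_fwhm <- function(tau_rise_s = 0.05, tau_decay_s = 0.3) {
  tmax <- tau_decay_s * 12
  tt <- seq(0, tmax, length.out = 8192)
  k <- ca_kernel(tt, 1, tau_rise_s, tau_decay_s)
  half <- max(k) / 2
  above <- which(k >= half)
  tt[above[length(above)]] - tt[above[1]]
}

# Half-sample symmetric reflection of index i into 1..n.
reflect_index <- function(i, n) {
  while (any(bad <- i < 1 | i > n)) {
    i[bad & i < 1] <- 1 - i[bad & i < 1]
    i[bad & i > n] <- 2 * n + 1 - i[bad & i > n]
  }
  i
}

# n x n Gaussian smoothing operator with reflective boundary; column sums are
# exactly 1, so applying it conserves the mean of any vector it multiplies.
gaussian_operator <- function(n, sigma_px) {
  if (sigma_px == 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_px))
  taps <- stats::dnorm(-r:r, sd = sigma_px)
  taps <- taps / sum(taps)
  W <- matrix(0, n, n)
  for (k in seq_along(taps)) {
    off <- k - r - 1L
    j <- reflect_index(seq_len(n) + off, n)
    W[cbind(seq_len(n), j)] <- W[cbind(seq_len(n), j)] + taps[k]
  }
  W
}

# Bilinear sample of matrix M at fractional (row, col) positions.
bilinear_sample <- function(M, row, col) {
  nr <- nrow(M); nc <- ncol(M)
  r0 <- pmin(pmax(floor(row), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(col), 1L), nc - 1L)
  fr <- row - r0
  fc <- col - c0
  i00 <- (c0 - 1L) * nr + r0
  M[i00]           * (1 - fr) * (1 - fc) +
  M[i00 + 1L]      * fr       * (1 - fc) +
  M[i00 + nr]      * (1 - fr) * fc +
  M[i00 + nr + 1L] * fr       * fc
}

# First index in x (a numeric vector) reaching threshold, with linear
# sub-sample interpolation between the straddling samples; NA if never.
first_crossing <- function(x, thr) {
  hit <- which(x >= thr)
  if (length(hit) == 0L) return(NA_real_)
  t1 <- hit[1L]
  if (t1 == 1L) return(1)
  (t1 - 1) + (thr - x[t1 - 1L]) / (x[t1] - x[t1 - 1L])
}
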