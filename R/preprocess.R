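# Denoising chain (dF/F0, Kalman stack filter, Gaussian blur), traces,
# and histogram-band signal-to-noise quantification.

#' Construct a fluorescence trace
#'
#' @param values Numeric vector of intensities (finite, length >= 1).
#' @param frame_interval_s Seconds between samples (> 0).
#' @param origin Free-text descriptor of the ROI the trace came from.
#' @return An object of class `wg_trace`.
#' @export
wg_trace <- function(values, frame_interval_s, origin = "") {
  wg_check(is.numeric(values) && length(values) >= 1L && all(is.finite(values)),
           "wavegraft_bad_trace", "values must be finite and non-empty")
  wg_check(is_scalar_num(frame_interval_s) && frame_interval_s > 0,
           "wavegraft_bad_metadata", "frame_interval_s must be positive")
  structure(list(values = as.numeric(values),
                 frame_interval_s = frame_interval_s,
                 origin = origin),
            class = "wg_trace")
}

#' Extract the mean-intensity trace of a region of interest
#'
#' @param stack A [frame_stack()].
#' @param roi A [disk_roi()] or axis-aligned [rect_region()].
#' @return A [wg_trace()] of per-frame ROI means.
#' @export
roi_trace <- function(stack, roi) {
  m <- roi_mask(roi, stack$height_px, stack$width_px)
  idx <- which(m)
  flat <- matrix(stack$frames, nrow = stack$n_frames)
  vals <- rowMeans(flat[, idx, drop = FALSE])
  wg_trace(vals, stack$frame_interval_s,
           origin = paste0(class(roi)[1], " roi"))
}

#' Background subtraction to dF/F0
#'
#' Per pixel, the baseline `F0` is a temporal percentile of that pixel's
#' intensity; the output is `(F - F0) / max(F0, eps)`, a dimensionless dF/F0
#' stack. The `eps` guard keeps already-baseline-subtracted (near-zero
#' baseline) pixels finite instead of raising.
#'
#' @param stack A [frame_stack()] with at least 5 frames.
#' @param baseline_percentile Temporal percentile (0-100) taken as the
#'   resting fluorescence; default 10.
#' @param eps Divisor floor in intensity units; default 1 (on 8/16-bit
#'   arbitrary-unit scales a baseline below 1 count is indistinguishable
#'   from zero).
#' @return A [frame_stack()] with `units = "dff"`.
#' @export
subtract_background <- function(stack, baseline_percentile = 10, eps = 1) {
  wg_check(inherits(stack, "frame_stack"), "wavegraft_bad_image",
           "stack must be a frame_stack")
  wg_check(stack$n_frames >= 5L, "wavegraft_bad_image",
           "background subtraction needs at least 5 frames")
  wg_check(baseline_percentile >= 0 && baseline_percentile <= 100,
           "wavegraft_bad_parameter", "baseline_percentile must be in [0, 100]")
  flat <- matrix(stack$frames, nrow = stack$n_frames)
  f0 <- apply(flat, 2L, stats::quantile, probs = baseline_percentile / 100,
              names = FALSE)
  out <- sweep(flat, 2L, f0, "-")
  out <- sweep(out, 2L, pmax(f0, eps), "/")
  frame_stack(array(out, dim(stack$frames)), stack$frame_interval_s,
              stack$pixel_size_um, units = "dff", seed = stack$seed)
}

#' Fixed-gain Kalman stack filter
#'
#' Per-pixel causal exponential recursion `E_1 = X_1`,
#' `E_t = gain * E_(t-1) + (1 - gain) * X_t`; the steady-state output
#' variance for i.i.d. input noise of variance `s^2` is
#' `s^2 (1 - gain) / (1 + gain)`. `gain = 0` returns the input unchanged.
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @param gain Smoothing gain in `[0, 1)`; default 0.8.
#' @return A filtered [frame_stack()] (same units as the input).
#' @export
kalman_filter <- function(stack, gain = 0.8) {
  wg_check(inherits(stack, "frame_stack"), "wavegraft_bad_image",
           "stack must be a frame_stack")
  wg_check(stack$n_frames >= 2L, "wavegraft_bad_image",
           "kalman_filter needs at least 2 frames")
  wg_check(is_scalar_num(gain) && gain >= 0 && gain < 1,
           "wavegraft_bad_parameter", "gain must lie in [0, 1)")
  fr <- stack$frames
  out <- fr
  for (t in 2:stack$n_frames)
    out[t, , ] <- gain * out[t - 1L, , ] + (1 - gain) * fr[t, , ]
  frame_stack(out, stack$frame_interval_s, stack$pixel_size_um,
              units = stack$units, seed = stack$seed)
}

#' Per-frame 2D Gaussian blur
#'
#' Separable Gaussian convolution with half-sample symmetric (reflective)
#' boundary handling; the operator's columns sum to 1, so the per-frame mean
#' intensity is conserved exactly. `sigma_px = 0` is the identity.
#'
#' @param stack A [frame_stack()].
#' @param sigma_px Gaussian standard deviation in pixels (>= 0).
#' @return A blurred [frame_stack()].
#' @export
gaussian_blur <- function(stack, sigma_px) {
  wg_check(inherits(stack, "frame_stack"), "wavegraft_bad_image",
           "stack must be a frame_stack")
  wg_check(is_scalar_num(sigma_px) && sigma_px >= 0,
           "wavegraft_bad_parameter", "sigma_px must be non-negative")
  if (sigma_px == 0) return(stack)
  Wr <- gaussian_operator(stack$height_px, sigma_px)
  Wc <- gaussian_operator(stack$width_px, sigma_px)
  out <- stack$frames
  for (t in seq_len(stack$n_frames))
    out[t, , ] <- Wr %*% stack$frames[t, , ] %*% t(Wc)
  frame_stack(out, stack$frame_interval_s, stack$pixel_size_um,
              units = stack$units, seed = stack$seed)
}

#' Define signal/noise intensity bands
#'
#' Closed intensity intervals on the camera's arbitrary-unit scale. The
#' defaults place the signal at 230-280 au between two noise bands
#' (150-230 and 280-400 au), the configuration used for EMCCD recordings on
#' a 0-4095-style scale.
#'
#' @param signal_band Length-2 numeric, the closed signal interval.
#' @param noise_bands List of length-2 numerics, closed noise intervals;
#'   each must be disjoint from the open interior of the signal band.
#' @return An object of class `snr_bands`.
#' @export
snr_bands <- function(signal_band = c(230, 280),
                      noise_bands = list(c(150, 230), c(280, 400))) {
  wg_check(length(signal_band) == 2L && signal_band[1] < signal_band[2],
           "wavegraft_bad_parameter", "signal_band must be an increasing pair")
  wg_check(length(noise_bands) >= 1L, "wavegraft_bad_parameter",
           "need at least one noise band")
  for (nb in noise_bands) {
    wg_check(length(nb) == 2L && nb[1] < nb[2], "wavegraft_bad_parameter",
             "each noise band must be an increasing pair")
    wg_check(nb[2] <= signal_band[1] || nb[1] >= signal_band[2],
             "wavegraft_bad_parameter",
             "noise bands must not overlap the signal band interior")
  }
  structure(list(signal_band = signal_band, noise_bands = noise_bands),
            class = "snr_bands")
}

in_band <- function(x, band) x >= band[1] & x <= band[2]

#' Histogram-band signal-to-noise ratio
#'
#' The count of pixels whose intensity falls in the signal band divided by
#' the count falling in the union of the noise bands. Pixels on a shared
#' band edge are counted in the signal band only.
#'
#' @param frame A 2D intensity matrix (or a [frame_stack()] single frame
#'   extracted by the caller).
#' @param bands An [snr_bands()] definition.
#' @return The dimensionless count ratio.
#' @section Errors: `wavegraft_empty_noise_band` when no pixel falls in any
#'   noise band (the ratio is undefined).
#' @export
snr_histogram <- function(frame, bands = snr_bands()) {
  wg_check(is.matrix(frame) || is.numeric(frame), "wavegraft_bad_image",
           "frame must be numeric")
  wg_check(inherits(bands, "snr_bands"), "wavegraft_bad_parameter",
           "bands must come from snr_bands()")
  x <- as.numeric(frame)
  sig <- in_band(x, bands$signal_band)
  noi <- Reduce(`|`, lapply(bands$noise_bands, function(b) in_band(x, b)))
  noi <- noi & !sig
  wg_check(sum(noi) > 0L, "wavegraft_empty_noise_band",
           "no pixels in any noise band: SNR undefined")
  sum(sig) / sum(noi)
}

#' Min-max normalize a trace to [0, 1]
#'
#' Affine map sending the minimum to 0 and the maximum to 1; idempotent and
#' order-preserving.
#'
#' @param trace A [wg_trace()] with non-constant values.
#' @return The normalized [wg_trace()].
#' @export
normalize_trace <- function(trace) {
  wg_check(inherits(trace, "wg_trace"), "wavegraft_bad_trace",
           "trace must be a wg_trace")
  rng <- range(trace$values)
  wg_check(rng[2] > rng[1], "wavegraft_constant_trace",
           "cannot normalize a constant trace")
  wg_trace((trace$values - rng[1]) / (rng[2] - rng[1]),
           trace$frame_interval_s, trace$origin)
}
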