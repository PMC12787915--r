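# Activation maps, reslice kymographs, conduction-velocity fits, and the
# monolayer-to-graft transmission delay.

#' Per-pixel adaptive-threshold activation map
#'
#' Each pixel activates at the first frame in the window where its intensity
#' reaches `(1 + threshold_pct/100)` times its own temporal mean over that
#' window. Relative thresholding gives every pixel its own criterion, which
#' is more sensitive than a single absolute threshold when resting
#' brightness varies across the field. Crossing times are refined by linear
#' interpolation between the straddling frames; pixels that never cross get
#' `NA` ("never activated").
#'
#' @param stack A [frame_stack()].
#' @param threshold_pct Percent rise above the per-pixel mean required to
#'   count as activation (> 0); default 20.
#' @param window Length-2 integer vector of 1-based frame indices
#'   (inclusive) to analyze; default the whole stack.
#' @return An object of class `activation_map`: `time_frames` (matrix of
#'   fractional absolute frame indices, `NA` = never), `threshold_pct`,
#'   `window`, `frame_interval_s`.
#' @export
activation_map <- function(stack, threshold_pct = 20, window = NULL) {
  wg_check(inherits(stack, "frame_stack"), "wavegraft_bad_image",
           "stack must be a frame_stack")
  wg_check(is_scalar_num(threshold_pct) && threshold_pct > 0,
           "wavegraft_bad_parameter", "threshold_pct must be positive")
  if (is.null(window)) window <- c(1L, stack$n_frames)
  wg_check(length(window) == 2L && window[1] >= 1 &&
             window[2] <= stack$n_frames && window[1] <= window[2],
           "wavegraft_bad_window", "window must lie within the stack")
  idx <- window[1]:window[2]
  flat <- matrix(stack$frames[idx, , , drop = FALSE], nrow = length(idx))
  thr <- (1 + threshold_pct / 100) * colMeans(flat)
  times <- vapply(seq_len(ncol(flat)), function(p) {
    first_crossing(flat[, p], thr[p])
  }, numeric(1))
  times <- times + (window[1] - 1) # back to absolute frame indices
  structure(list(
    time_frames = matrix(times, stack$height_px, stack$width_px),
    threshold_pct = threshold_pct,
    window = as.integer(window),
    frame_interval_s = stack$frame_interval_s,
    pixel_size_um = stack$pixel_size_um
  ), class = "activation_map")
}

#' Activation times in seconds
#'
#' @param map An [activation_map()].
#' @return Matrix of activation times in seconds from the recording start
#'   (frame 1 = 0 s); `NA` where a pixel never activated.
#' @export
activation_seconds <- function(map) {
  wg_check(inherits(map, "activation_map"), "wavegraft_bad_parameter",
           "map must be an activation_map")
  (map$time_frames - 1) * map$frame_interval_s
}

#' @export
plot.activation_map <- function(x, ...) {
  tf <- x$time_frames
  graphics::image(t(tf)[, rev(seq_len(nrow(tf))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  axes = FALSE, asp = nrow(tf) / ncol(tf),
                  main = "activation time (frames)", ...)
  invisible(x)
}

#' Reslice a stack into a space-time (kymograph) map
#'
#' For each position `s` along the region's long axis and each frame `t`,
#' the intensity is averaged across the region's short axis, producing a
#' `width_px x n_frames` map in which a propagating wavefront appears as a
#' tilted bright line. Off-axis rectangles are sampled bilinearly.
#'
#' @param stack A [frame_stack()].
#' @param region A [rect_region()] lying fully inside the image.
#' @return An object of class `kymograph`: `intensity` (space x time),
#'   `frame_interval_s`, `pixel_size_um`, `source_region`.
#' @export
reslice_kymograph <- function(stack, region) {
  wg_check(inherits(stack, "frame_stack"), "wavegraft_bad_image",
           "stack must be a frame_stack")
  wg_check(inherits(region, "rect_region"), "wavegraft_bad_region",
           "region must be a rect_region")
  th <- region$orientation_deg * pi / 180
  u <- c(sin(th), cos(th))   # long axis (row, col) direction
  v <- c(cos(th), -sin(th))  # short axis direction
  s <- seq_len(region$width_px) - 1L
  j <- seq_len(region$height_px) - 1L
  rows <- region$origin_row + outer(s * u[1], j * v[1], "+")
  cols <- region$origin_col + outer(s * u[2], j * v[2], "+")
  inside <- rows >= 1 & rows <= stack$height_px &
    cols >= 1 & cols <= stack$width_px
  wg_check(all(inside), "wavegraft_bad_region",
           "region extends outside the image")
  K <- matrix(0, region$width_px, stack$n_frames)
  aligned <- region$orientation_deg == 0
  for (t in seq_len(stack$n_frames)) {
    fr <- stack$frames[t, , ]
    samp <- if (aligned) {
      fr[cbind(as.vector(rows), as.vector(cols))]
    } else {
      bilinear_sample(fr, as.vector(rows), as.vector(cols))
    }
    K[, t] <- rowMeans(matrix(samp, region$width_px, region$height_px))
  }
  structure(list(
    intensity = K,
    frame_interval_s = stack$frame_interval_s,
    pixel_size_um = stack$pixel_size_um,
    source_region = region
  ), class = "kymograph")
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(t(x$intensity), col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "time (frames)", ylab = "space (px)", axes = FALSE,
                  ...)
  invisible(x)
}

# Rising-edge time (frames, fractional) per spatial row of a kymograph
# window, using the activation-map relative-threshold rule.
kymo_front_times <- function(K, cols, threshold_pct) {
  sub <- K[, cols, drop = FALSE]
  mu <- rowMeans(sub)
  thr <- (1 + threshold_pct / 100) * mu
  vapply(seq_len(nrow(sub)), function(s) {
    first_crossing(sub[s, ], thr[s])
  }, numeric(1)) + (cols[1] - 1)
}

#' Fit wavefront slope(s) in a kymograph to estimate conduction velocity
#'
#' Per wavefront, the rising-edge time at each spatial position is found
#' with the same relative-threshold rule as [activation_map()], and the
#' front line `time = s / v + c` is fit by least squares. With the space
#' axis vertical and the time axis horizontal, the angle `alpha` between
#' the front line and the time axis satisfies `v = tan(alpha)` in px/frame.
#' When a stimulus train is given, one front is extracted per pulse (within
#' that pulse's period) and the per-wave speeds are averaged.
#'
#' A front whose fitted traversal is too close to instantaneous (slope below
#' `min_slope_frames_per_px`) or whose fit residual exceeds
#' `max_residual_frames` is flagged degenerate; if all fronts are
#' degenerate the velocity is reported as `Inf` (wave effectively
#' simultaneous across the field at this frame rate).
#'
#' @param kymo A [reslice_kymograph()] result.
#' @param stim Optional [build_stimulus_train()] delimiting one front per
#'   pulse.
#' @param threshold_pct Rise criterion, percent above the per-row mean;
#'   default 20.
#' @param min_slope_frames_per_px Smallest resolvable slope in frames/px;
#'   fronts flatter than this are degenerate. Default 0.02 (50 px/frame).
#' @param max_residual_frames RMS residual bound in frames above which a
#'   fit is flagged degenerate; default 3.
#' @return An object of class `wavefront_fit`: `slope_px_per_frame` (mean
#'   front speed, px/frame; `Inf` if degenerate), `alpha_deg`,
#'   `velocity_um_per_s` (`NA` without pixel calibration),
#'   `fit_residual` (mean RMS, frames), `n_waves`, `degenerate`, and the
#'   per-wave table `waves`.
#' @export
fit_wavefront <- function(kymo, stim = NULL, threshold_pct = 20,
                          min_slope_frames_per_px = 0.02,
                          max_residual_frames = 3) {
  wg_check(inherits(kymo, "kymograph"), "wavegraft_bad_parameter",
           "kymo must be a kymograph")
  K <- kymo$intensity
  n_t <- ncol(K)
  dt <- kymo$frame_interval_s
  windows <- if (is.null(stim)) {
    list(seq_len(n_t))
  } else {
    lapply(stim$onset_times_s, function(on) {
      f0 <- max(1L, floor(on / dt) + 1L)
      f1 <- min(n_t, f0 + ceiling(stim$period_s / dt) - 1L)
      if (f1 > f0) f0:f1 else NULL
    })
  }
  windows <- Filter(Negate(is.null), windows)
  waves <- list()
  for (w in windows) {
    tf <- kymo_front_times(K, w, threshold_pct)
    s <- which(!is.na(tf))
    if (length(s) < 3L) next
    fit <- stats::lm.fit(cbind(1, s), tf[s])
    b <- fit$coefficients[2L]
    rms <- sqrt(mean(fit$residuals^2))
    degen <- abs(b) < min_slope_frames_per_px || rms > max_residual_frames
    waves[[length(waves) + 1L]] <- data.frame(
      slope_frames_per_px = b,
      speed_px_per_frame = if (degen) Inf else abs(1 / b),
      rms_frames = rms, n_points = length(s), degenerate = degen)
  }
  wg_check(length(waves) > 0L, "wavegraft_no_front",
           "no detectable wavefront in the kymograph")
  waves <- do.call(rbind, waves)
  good <- !waves$degenerate
  if (any(good)) {
    v <- mean(waves$speed_px_per_frame[good])
    res <- mean(waves$rms_frames[good])
    degenerate <- FALSE
  } else {
    v <- Inf
    res <- mean(waves$rms_frames)
    degenerate <- TRUE
  }
  vel <- if (!is.null(kymo$pixel_size_um) && is.finite(v))
    v * kymo$pixel_size_um / dt else NA_real_
  structure(list(
    slope_px_per_frame = v,
    alpha_deg = atan(v) * 180 / pi,
    velocity_um_per_s = vel,
    fit_residual = res,
    n_waves = sum(good),
    degenerate = degenerate,
    waves = waves,
    threshold_pct = threshold_pct
  ), class = "wavefront_fit")
}

#' @export
print.wavefront_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<wavefront_fit> degenerate: wave effectively simultaneous across the field\n")
  } else {
    cat(sprintf("<wavefront_fit> %.3g px/frame over %d wave(s) (alpha %.1f deg, RMS %.2f frames)\n",
                x$slope_px_per_frame, x$n_waves, x$alpha_deg, x$fit_residual))
    if (!is.na(x$velocity_um_per_s))
      cat(sprintf("  calibrated velocity: %.4g um/s\n", x$velocity_um_per_s))
  }
  invisible(x)
}

#' Monolayer-to-graft transmission delay
#'
#' Matches graft calcium-transient peaks to adjacent-monolayer peaks with
#' the [classify_synchronization()] rule and reports the per-wave delays.
#' Because a not-yet-coupled graft also fires spontaneously, some matches
#' are chance coincidences with scattered delays; with `robust = TRUE`
#' (default) the summary statistics are computed on the modal delay cluster
#' (delays within `median +/- max(3 MAD, 2 frames)`), while the full
#' matched list is always returned.
#'
#' @param x A [frame_stack()] (traces are extracted from the two ROIs) or a
#'   list of two [wg_trace()] objects `list(monolayer, graft)`.
#' @param monolayer_roi,graft_roi ROIs ([disk_roi()] or axis-aligned
#'   [rect_region()]) when `x` is a stack; the monolayer ROI should sit
#'   adjacent to the graft.
#' @param window_s Matching window, seconds; default 0.8 times the median
#'   monolayer peak spacing.
#' @param min_prominence,min_separation_s Peak-detection settings passed to
#'   [detect_peaks()] on both (normalized) traces.
#' @param lead_s Tolerance for graft peaks slightly preceding the monolayer
#'   peak (noise jitters both peak times, so an instantly coupled graft
#'   produces delays scattered around zero); the effective matching window
#'   is `(r - lead_s, r + window_s]`. Default 2 frames.
#' @param robust Filter chance coincidences before averaging (see above).
#' @return An object of class `transmission_delay`: `mean_frames`,
#'   `sd_frames`, `mean_s`, `sd_s`, per-wave `delays_s` (retained cluster),
#'   `delays_all_s` (every matched delay), `n_waves`, `n_excluded`,
#'   `frame_interval_s`, and the underlying `sync` report.
#' @section Errors: `wavegraft_no_transmission` when no wave is matched.
#' @export
transmission_delay <- function(x, monolayer_roi = NULL, graft_roi = NULL,
                               window_s = NULL, min_prominence = 0.25,
                               min_separation_s = 0.25, lead_s = NULL,
                               robust = TRUE) {
  if (inherits(x, "frame_stack")) {
    wg_check(!is.null(monolayer_roi) && !is.null(graft_roi),
             "wavegraft_bad_parameter",
             "supply monolayer_roi and graft_roi with a frame_stack")
    mono <- roi_trace(x, monolayer_roi)
    gft <- roi_trace(x, graft_roi)
  } else if (is.list(x) && length(x) == 2L &&
               inherits(x[[1]], "wg_trace") && inherits(x[[2]], "wg_trace")) {
    mono <- x[[1]]; gft <- x[[2]]
  } else {
    wg_stop("wavegraft_bad_parameter",
            "x must be a frame_stack or a list of two wg_trace objects")
  }
  dt <- mono$frame_interval_s
  pk_m <- detect_peaks(normalize_trace(mono), min_prominence, min_separation_s)
  pk_g <- detect_peaks(normalize_trace(gft), min_prominence, min_separation_s)
  wg_check(length(pk_m$peak_times_s) >= 1L, "wavegraft_no_transmission",
           "no monolayer waves detected")
  if (is.null(window_s)) {
    sp <- stats::median(diff(pk_m$peak_times_s))
    wg_check(is.finite(sp), "wavegraft_bad_parameter",
             "cannot infer window_s from a single monolayer wave; supply it")
    window_s <- 0.8 * sp
  }
  if (is.null(lead_s)) lead_s <- 2 * dt
  # match against lead-shifted references, then restore true delays
  sync <- classify_synchronization(pk_m$peak_times_s - lead_s,
                                   pk_g, window_s + lead_s)
  wg_check(sync$n_transmitted > 0L, "wavegraft_no_transmission",
           "no transmitted waves matched within the window")
  # express the embedded report in the unshifted reference frame
  sync$delays_s <- sync$delays_s - lead_s
  sync$reference_times_s <- sync$reference_times_s + lead_s
  sync$window_s <- window_s
  sync$lead_s <- lead_s
  all_d <- sync$delays_s
  keep <- rep(TRUE, length(all_d))
  if (robust && length(all_d) > 2L) {
    med <- stats::median(all_d)
    band <- max(3 * stats::mad(all_d), 2 * dt)
    keep <- abs(all_d - med) <= band
  }
  d <- all_d[keep]
  structure(list(
    mean_s = mean(d),
    sd_s = if (length(d) > 1L) stats::sd(d) else 0,
    mean_frames = mean(d) / dt,
    sd_frames = (if (length(d) > 1L) stats::sd(d) else 0) / dt,
    delays_s = d,
    delays_all_s = all_d,
    n_waves = length(d),
    n_excluded = sum(!keep),
    frame_interval_s = dt,
    window_s = window_s,
    lead_s = lead_s,
    sync = sync
  ), class = "transmission_delay")
}

#' @export
print.transmission_delay <- function(x, ...) {
  cat(sprintf("<transmission_delay> %.2f +/- %.2f frames (%.3f +/- %.3f s) over %d wave(s)\n",
              x$mean_frames, x$sd_frames, x$mean_s, x$sd_s, x$n_waves))
  if (x$n_excluded > 0)
    cat(sprintf("  %d chance-coincidence match(es) excluded from the cluster\n",
                x$n_excluded))
  invisible(x)
}
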