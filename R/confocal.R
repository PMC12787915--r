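# Temporal decoding of single confocal raster-scan frames: in a slow
# top-to-bottom scan of a periodically firing sheet, each firing paints a
# horizontal bright band, so band geometry (row spacing, row width) encodes
# time through the per-line acquisition interval.

#' Averaged side projection of a raster frame
#'
#' Mean intensity across the columns of a rectangular averaging region, one
#' value per image row of the region.
#'
#' @param frame A [raster_scan_frame()].
#' @param region An axis-aligned [rect_region()] inside the frame; default
#'   the full frame.
#' @return Numeric profile over the region's rows; the attribute `"rows"`
#'   holds the absolute 1-based row indices.
#' @export
side_projection <- function(frame, region = NULL) {
  wg_check(inherits(frame, "raster_scan_frame"), "wavegraft_bad_image",
           "frame must be a raster_scan_frame")
  if (is.null(region))
    region <- rect_region(1, 1, frame$height_px, frame$width_px)
  wg_check(region$orientation_deg == 0, "wavegraft_bad_region",
           "side projection uses axis-aligned regions")
  r1 <- region$origin_row; r2 <- r1 + region$height_px - 1L
  c1 <- region$origin_col; c2 <- c1 + region$width_px - 1L
  wg_check(r1 >= 1 && c1 >= 1 && r2 <= frame$height_px &&
             c2 <= frame$width_px, "wavegraft_bad_region",
           "region extends outside the frame")
  prof <- rowMeans(frame$image[r1:r2, c1:c2, drop = FALSE])
  attr(prof, "rows") <- r1:r2
  prof
}

# Width of the band around peak index p at height h - prom/2, by linear
# interpolation on each flank.
half_prominence_width <- function(v, p, prom) {
  level <- v[p] - prom / 2
  l <- p
  while (l > 1L && v[l - 1L] >= level) l <- l - 1L
  left <- if (l == 1L || v[l] == level) as.numeric(l) else
    l - (v[l] - level) / (v[l] - v[l - 1L])
  r <- p
  n <- length(v)
  while (r < n && v[r + 1L] >= level) r <- r + 1L
  right <- if (r == n || v[r] == level) as.numeric(r) else
    r + (v[r] - level) / (v[r] - v[r + 1L])
  right - left
}

#' Detect fluorescence bands in a side-projection profile
#'
#' Prominence-filtered local maxima with parabolic sub-pixel center
#' refinement and full widths at half prominence. Set `refine = FALSE` to
#' report integer row positions, mimicking distances read directly off the
#' image.
#'
#' @param profile Numeric profile (length >= 3), e.g. from
#'   [side_projection()].
#' @param min_prominence Minimum prominence as a fraction of the profile
#'   range; default 0.25.
#' @param refine Parabolic sub-pixel refinement of band centers; default
#'   `TRUE`.
#' @return An object of class `band_set`: `band_centers_px` (strictly
#'   increasing row positions), `band_widths_px` (full widths at half
#'   prominence), `prominences`, `projection`. May be empty.
#' @export
detect_bands <- function(profile, min_prominence = 0.25, refine = TRUE) {
  wg_check(is.numeric(profile) && length(profile) >= 3L,
           "wavegraft_bad_trace", "profile must be numeric, length >= 3")
  v <- as.numeric(profile)
  rng <- diff(range(v))
  peaks <- local_maxima(v)
  if (length(peaks) && rng > 0) {
    prom <- peak_prominence(v, peaks)
    keep <- prom >= min_prominence * rng
    peaks <- peaks[keep]; prom <- prom[keep]
  } else prom <- numeric(0)
  centers <- as.numeric(peaks)
  widths <- numeric(length(peaks))
  for (i in seq_along(peaks)) {
    p <- peaks[i]
    if (refine && p > 1L && p < length(v)) {
      a <- v[p - 1L]; b <- v[p]; cc <- v[p + 1L]
      den <- a - 2 * b + cc
      if (den < 0) centers[i] <- p + (a - cc) / (2 * den)
    }
    widths[i] <- half_prominence_width(v, p, prom[i])
  }
  structure(list(
    band_centers_px = centers,
    band_widths_px = widths,
    prominences = prom,
    projection = v
  ), class = "band_set")
}

#' Seconds per scan line of a raster frame
#'
#' Each of the frame's rows is treated as acquired instantaneously, so one
#' line takes `frame_time_s / height_px` seconds; 1-based row `l` is
#' acquired `(l - 1)` line times into the frame.
#'
#' @param frame A [raster_scan_frame()].
#' @return Seconds per scan line.
#' @examples
#' line_time(raster_scan_frame(matrix(0, 1024, 8), 36)) # 36/1024
#' @export
line_time <- function(frame) {
  wg_check(inherits(frame, "raster_scan_frame"), "wavegraft_bad_image",
           "frame must be a raster_scan_frame")
  frame$frame_time_s / frame$height_px
}

#' Decode the sheet firing period from band spacing
#'
#' A sheet firing with period `T` paints bands every
#' `T * height_px / frame_time_s` rows, so the period is the band spacing
#' times the per-line time.
#'
#' @param band_spacing_px Row distance between adjacent band centers
#'   (>= 0).
#' @param frame The [raster_scan_frame()] supplying the line time.
#' @return List with `period_s` (full precision) and `period_s_rounded`
#'   (2 decimals, half-up).
#' @examples
#' fr <- raster_scan_frame(matrix(0, 1024, 8), 36)
#' decode_period(21, fr)$period_s_rounded # 0.74
#' @export
decode_period <- function(band_spacing_px, frame) {
  wg_check(is_scalar_num(band_spacing_px) && band_spacing_px >= 0,
           "wavegraft_bad_parameter", "band_spacing_px must be >= 0")
  p <- band_spacing_px * line_time(frame)
  list(period_s = p, period_s_rounded = round_half_up(p, 2))
}

#' Decode the calcium-transient duration from band width
#'
#' A transient lasting `D` seconds keeps `D * height_px / frame_time_s`
#' consecutive rows bright, so the duration is the band width times the
#' per-line time.
#'
#' @param band_width_px Band full width in rows (> 0).
#' @param frame The [raster_scan_frame()] supplying the line time.
#' @return List with `duration_s` (full precision) and
#'   `duration_s_rounded` (1 decimal, half-up).
#' @examples
#' fr <- raster_scan_frame(matrix(0, 1024, 8), 36)
#' decode_duration(29, fr)$duration_s_rounded # 1.0
#' @export
decode_duration <- function(band_width_px, frame) {
  wg_check(is_scalar_num(band_width_px) && band_width_px > 0,
           "wavegraft_bad_parameter", "band_width_px must be positive")
  d <- band_width_px * line_time(frame)
  list(duration_s = d, duration_s_rounded = round_half_up(d, 1))
}

#' Full raster-frame temporal decode
#'
#' Convenience pipeline: [side_projection()], [detect_bands()], then the
#' median adjacent band spacing decoded to the firing period and the median
#' band width decoded to the transient duration.
#'
#' @param frame A [raster_scan_frame()].
#' @param region Optional averaging [rect_region()]; default full frame.
#' @param min_prominence Band-detection prominence threshold; default 0.25.
#' @param stim_period_s Optional stimulation period for a commensurability
#'   verdict against the frame scan time (see [check_commensurability()]).
#' @param tol Commensurability tolerance; default 0.01.
#' @return List with `bands`, `period_s`, `period_s_rounded`,
#'   `duration_s`, `duration_s_rounded`, `spacings_px`, and (when
#'   `stim_period_s` is given) `commensurability`.
#' @export
decode_raster <- function(frame, region = NULL, min_prominence = 0.25,
                          stim_period_s = NULL, tol = 0.01) {
  prof <- side_projection(frame, region)
  bands <- detect_bands(prof, min_prominence)
  wg_check(length(bands$band_centers_px) >= 2L, "wavegraft_no_front",
           "need at least two bands to decode a period")
  sp <- diff(bands$band_centers_px)
  per <- decode_period(stats::median(sp), frame)
  dur <- decode_duration(stats::median(bands$band_widths_px), frame)
  out <- list(bands = bands, spacings_px = sp,
              period_s = per$period_s,
              period_s_rounded = per$period_s_rounded,
              duration_s = dur$duration_s,
              duration_s_rounded = dur$duration_s_rounded)
  if (!is.null(stim_period_s))
    out$commensurability <-
      check_commensurability(stim_period_s, frame$frame_time_s, tol)
  out
}

#' Check commensurability of stimulation period and frame scan time
#'
#' Clean vertically aligned band patterns require the frame scan time `t2`
#' to be an integer multiple of the stimulation period `t1`; otherwise the
#' band pattern drifts between frames and becomes disordered.
#'
#' @param t1_s Stimulation period, seconds (> 0).
#' @param t2_s Frame scan time, seconds (> 0).
#' @param tol Relative tolerance on the integer multiple; default 0.01.
#' @return List with `verdict` (`"aligned"` or `"disordered"`), `multiple`
#'   (nearest integer `round(t2/t1)`), `residual` (`t2/t1 - multiple`), and
#'   `ratio`.
#' @examples
#' check_commensurability(1.0, 36)$verdict # aligned, multiple 36
#' @export
check_commensurability <- function(t1_s, t2_s, tol = 0.01) {
  wg_check(is_scalar_num(t1_s) && t1_s > 0, "wavegraft_bad_parameter",
           "t1_s must be positive")
  wg_check(is_scalar_num(t2_s) && t2_s > 0, "wavegraft_bad_parameter",
           "t2_s must be positive")
  ratio <- t2_s / t1_s
  m <- round(ratio)
  resid <- ratio - m
  aligned <- m >= 1 && abs(resid) <= tol * m
  list(verdict = if (aligned) "aligned" else "disordered",
       multiple = as.integer(m), residual = resid, ratio = ratio)
}
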