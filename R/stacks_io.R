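# Movie/stack data model and TIFF + JSON-sidecar input/output.

#' Construct a frame stack
#'
#' The core movie container: a time-ordered set of 2D grayscale frames with
#' the acquisition metadata every temporal computation needs (seconds per
#' frame, optionally micrometers per pixel).
#'
#' @param frames 3D numeric array indexed `(frame, row, col)`, or a list of
#'   equally sized matrices. Row 1 is the image top; indices are 1-based.
#' @param frame_interval_s Seconds between consecutive frames (> 0).
#' @param pixel_size_um Micrometers per pixel, or `NULL` when the recording
#'   is uncalibrated (velocities are then reported in px/frame only).
#' @param units `"au"` for raw acquisition data (intensities must be finite
#'   and non-negative) or `"dff"` for derived dF/F0 stacks (negative dips
#'   from noise are allowed).
#' @param seed Optional integer recorded as provenance when the stack was
#'   synthesized.
#' @return An object of class `frame_stack` with fields `frames`, `n_frames`,
#'   `height_px`, `width_px`, `frame_interval_s`, `pixel_size_um`, `units`.
#' @seealso [read_stack()], [write_stack()]
#' @export
frame_stack <- function(frames, frame_interval_s, pixel_size_um = NULL,
                        units = c("au", "dff"), seed = NULL) {
  units <- match.arg(units)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    wg_check(length(dims) == 1L && length(dims[[1L]]) == 2L,
             "wavegraft_bad_image", "frames must be equally sized matrices")
    a <- array(0, c(length(frames), dims[[1L]][1L], dims[[1L]][2L]))
    for (i in seq_along(frames)) a[i, , ] <- frames[[i]]
    frames <- a
  }
  wg_check(is.array(frames) && length(dim(frames)) == 3L,
           "wavegraft_bad_image", "frames must be a (t, row, col) array")
  storage.mode(frames) <- "double"
  wg_check(dim(frames)[1L] >= 1L, "wavegraft_bad_image",
           "a stack needs at least one frame")
  wg_check(all(is.finite(frames)), "wavegraft_bad_image",
           "all intensities must be finite")
  if (units == "au")
    wg_check(all(frames >= 0), "wavegraft_bad_image",
             "raw intensities must be non-negative")
  wg_check(is_scalar_num(frame_interval_s) && frame_interval_s > 0,
           "wavegraft_bad_metadata", "frame_interval_s must be positive")
  if (!is.null(pixel_size_um))
    wg_check(is_scalar_num(pixel_size_um) && pixel_size_um > 0,
             "wavegraft_bad_metadata", "pixel_size_um must be positive")
  structure(list(
    frames = frames,
    n_frames = dim(frames)[1L],
    height_px = dim(frames)[2L],
    width_px = dim(frames)[3L],
    frame_interval_s = frame_interval_s,
    pixel_size_um = pixel_size_um,
    units = units,
    seed = seed
  ), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("<frame_stack> %d frames of %d x %d px, %.4g s/frame (%.3g fps)\n",
              x$n_frames, x$height_px, x$width_px, x$frame_interval_s,
              1 / x$frame_interval_s))
  if (!is.null(x$pixel_size_um))
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size_um))
  cat(sprintf("  units: %s; intensity range [%.4g, %.4g]\n",
              x$units, min(x$frames), max(x$frames)))
  invisible(x)
}

#' Construct a confocal raster-scan frame
#'
#' A single slow raster scan in which each image row was acquired at a
#' different time: row `l` (1-based, top to bottom) is treated as acquired at
#' `(l - 1) * frame_time_s / height_px` seconds into the frame.
#'
#' @param image 2D numeric matrix `(row, col)`.
#' @param frame_time_s Seconds to acquire the full frame (> 0).
#' @return An object of class `raster_scan_frame` with fields `image`,
#'   `height_px`, `width_px`, `frame_time_s`, `scan_order`.
#' @seealso [line_time()], [decode_period()]
#' @export
raster_scan_frame <- function(image, frame_time_s) {
  wg_check(is.matrix(image) && nrow(image) >= 2L, "wavegraft_bad_image",
           "image must be a matrix with at least 2 rows")
  wg_check(is_scalar_num(frame_time_s) && frame_time_s > 0,
           "wavegraft_bad_metadata", "frame_time_s must be positive")
  structure(list(
    image = image,
    height_px = nrow(image),
    width_px = ncol(image),
    frame_time_s = frame_time_s,
    scan_order = "top-to-bottom"
  ), class = "raster_scan_frame")
}

#' Build a periodic stimulus train
#'
#' Field-stimulation metadata: `n_pulses` onsets spaced exactly `period_s`
#' apart starting at `t0_s`.
#'
#' @param period_s Inter-pulse interval in seconds (must exceed
#'   `pulse_duration_s`).
#' @param pulse_duration_s Pulse width in seconds (> 0).
#' @param n_pulses Number of pulses (>= 1).
#' @param t0_s Onset of the first pulse, seconds.
#' @param amplitude_V Pulse amplitude in volts (metadata only).
#' @return An object of class `stimulus_train` with `onset_times_s`,
#'   `pulse_duration_s`, `period_s`, `amplitude_V`.
#' @examples
#' build_stimulus_train(1.0, 0.02, 42)$onset_times_s[1:3]
#' @export
build_stimulus_train <- function(period_s, pulse_duration_s, n_pulses,
                                 t0_s = 0, amplitude_V = NA_real_) {
  wg_check(is_scalar_num(pulse_duration_s) && pulse_duration_s > 0,
           "wavegraft_bad_stimulus", "pulse_duration_s must be positive")
  wg_check(is_scalar_num(period_s) && period_s > pulse_duration_s,
           "wavegraft_bad_stimulus", "period_s must exceed pulse_duration_s")
  wg_check(is_scalar_num(n_pulses) && n_pulses >= 1 &&
             n_pulses == as.integer(n_pulses),
           "wavegraft_bad_stimulus", "n_pulses must be a positive integer")
  structure(list(
    onset_times_s = t0_s + (seq_len(n_pulses) - 1) * period_s,
    pulse_duration_s = pulse_duration_s,
    period_s = period_s,
    amplitude_V = amplitude_V
  ), class = "stimulus_train")
}

#' Define a rectangular region of interest
#'
#' The rectangle's long axis (length `width_px`) points along image columns
#' rotated by `orientation_deg`; its short axis (`height_px`) is
#' perpendicular. `orientation_deg = 0` gives an axis-aligned rectangle whose
#' rows run `origin_row .. origin_row + height_px - 1`.
#'
#' @param origin_row,origin_col 1-based pixel coordinates of the rectangle
#'   corner from which both axes emanate.
#' @param height_px Short-axis extent in pixels (>= 1).
#' @param width_px Long-axis extent in pixels (>= 2).
#' @param orientation_deg Angle of the long axis relative to image columns,
#'   degrees (positive rotates toward increasing rows).
#' @return An object of class `rect_region`.
#' @seealso [reslice_kymograph()], [side_projection()]
#' @export
rect_region <- function(origin_row, origin_col, height_px, width_px,
                        orientation_deg = 0) {
  wg_check(height_px >= 1 && width_px >= 2, "wavegraft_bad_region",
           "need height_px >= 1 and width_px >= 2")
  structure(list(origin_row = origin_row, origin_col = origin_col,
                 height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 orientation_deg = orientation_deg),
            class = "rect_region")
}

#' Define a disk region of interest
#'
#' @param center_row,center_col 1-based pixel coordinates of the disk center.
#' @param radius_px Radius in pixels (> 0). A pixel belongs to the disk when
#'   its center lies within `radius_px` of the disk center.
#' @return An object of class `disk_roi`.
#' @export
disk_roi <- function(center_row, center_col, radius_px) {
  wg_check(radius_px > 0, "wavegraft_bad_region", "radius_px must be positive")
  structure(list(center_row = center_row, center_col = center_col,
                 radius_px = radius_px), class = "disk_roi")
}

roi_mask <- function(roi, height_px, width_px) {
  if (inherits(roi, "disk_roi")) {
    rr <- matrix(seq_len(height_px), height_px, width_px)
    cc <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
    m <- (rr - roi$center_row)^2 + (cc - roi$center_col)^2 <= roi$radius_px^2
  } else if (inherits(roi, "rect_region")) {
    wg_check(roi$orientation_deg == 0, "wavegraft_bad_region",
             "mask extraction supports axis-aligned rectangles only")
    m <- matrix(FALSE, height_px, width_px)
    m[roi$origin_row:(roi$origin_row + roi$height_px - 1L),
      roi$origin_col:(roi$origin_col + roi$width_px - 1L)] <- TRUE
  } else {
    wg_stop("wavegraft_bad_region", "unsupported ROI type")
  }
  wg_check(any(m), "wavegraft_bad_region", "ROI covers no pixels")
  m
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a frame stack to a multi-page TIFF with a JSON sidecar
#'
#' Integer-valued stacks within the chosen bit depth are written bit-exactly
#' as 8- or 16-bit grayscale pages. Stacks with fractional or negative values
#' (e.g. dF/F0) are min-max affine-scaled into 32-bit storage, with the scale
#' recorded in the sidecar so [read_stack()] can invert it. The sidecar also
#' carries `frame_interval_s`, `pixel_size_um`, units, the generator seed (if
#' any) and the tool version.
#'
#' @param stack A [frame_stack()].
#' @param path Destination TIFF path; the sidecar is written next to it with
#'   extension `.json`.
#' @param bits_per_sample 8 or 16 for integer data; ignored (32 used) when
#'   the data require float storage.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16) {
  wg_check(inherits(stack, "frame_stack"), "wavegraft_bad_image",
           "stack must be a frame_stack")
  wg_check(bits_per_sample %in% c(8, 16), "wavegraft_bad_metadata",
           "bits_per_sample must be 8 or 16")
  dir_ok <- dir.exists(dirname(path))
  wg_check(dir_ok, "wavegraft_unwritable", sprintf(
    "cannot write '%s': directory does not exist", path))
  fr <- stack$frames
  maxint <- 2^bits_per_sample - 1
  integral <- all(fr == floor(fr)) && min(fr) >= 0 && max(fr) <= maxint
  if (integral) {
    scale <- NULL
    pages <- lapply(seq_len(stack$n_frames),
                    function(t) fr[t, , ] / maxint)
    bits <- bits_per_sample
  } else {
    lo <- min(fr); hi <- max(fr)
    slope <- if (hi > lo) hi - lo else 1
    scale <- list(offset = lo, slope = slope)
    pages <- lapply(seq_len(stack$n_frames),
                    function(t) (fr[t, , ] - lo) / slope)
    bits <- 32
  }
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = bits,
                    compression = "none", reduce = FALSE)
    TRUE
  }, error = function(e) FALSE)
  wg_check(ok, "wavegraft_unwritable", sprintf("cannot write '%s'", path))
  meta <- list(
    frame_interval_s = stack$frame_interval_s,
    pixel_size_um = stack$pixel_size_um,
    units = stack$units,
    bits_per_sample = bits,
    scale = scale,
    provenance = list(
      tool = "wavegraft",
      version = as.character(utils::packageVersion("wavegraft")),
      seed = stack$seed
    )
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a frame stack
#'
#' Metadata come from the JSON sidecar written by [write_stack()] when
#' present; explicit arguments override sidecar values, and
#' `frame_interval_s` must be available from one of the two sources.
#'
#' @param path TIFF file path.
#' @param frame_interval_s Seconds per frame (overrides the sidecar).
#' @param pixel_size_um Micrometers per pixel (overrides the sidecar).
#' @return A [frame_stack()].
#' @section Errors: `wavegraft_missing_file` if `path` does not exist;
#'   `wavegraft_bad_image` for non-grayscale or ragged pages;
#'   `wavegraft_bad_metadata` for a missing or non-positive frame interval.
#' @export
read_stack <- function(path, frame_interval_s = NULL, pixel_size_um = NULL) {
  wg_check(file.exists(path), "wavegraft_missing_file",
           sprintf("no such file: '%s'", path))
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  bits <- meta$bits_per_sample
  as_is <- is.null(bits) || bits %in% c(8, 16)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  wg_check(all(vapply(pages, function(p) length(dim(p)) == 2L, logical(1))),
           "wavegraft_bad_image", "stack pages must be single-channel grayscale")
  dims <- unique(lapply(pages, dim))
  wg_check(length(dims) == 1L, "wavegraft_bad_image",
           "stack pages have inconsistent dimensions")
  fr <- array(0, c(length(pages), dims[[1L]][1L], dims[[1L]][2L]))
  for (t in seq_along(pages)) fr[t, , ] <- pages[[t]]
  if (!is.null(meta$scale)) # invert the affine storage scale for float data
    fr <- fr * meta$scale$slope + meta$scale$offset
  fi <- frame_interval_s %||% meta$frame_interval_s
  wg_check(!is.null(fi), "wavegraft_bad_metadata",
           "frame_interval_s missing: supply it or provide a sidecar")
  wg_check(is_scalar_num(fi) && fi > 0, "wavegraft_bad_metadata",
           "frame_interval_s must be positive")
  px <- pixel_size_um %||% meta$pixel_size_um
  units <- meta$units %||% "au"
  frame_stack(fr, fi, px, units = units,
              seed = meta$provenance$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
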