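# Stimulus-locked synchronization statistics, the coincidence null, and the
# cell-chain model of per-contact transmission time.

# Indices of local maxima, plateau-aware: first sample of any run whose
# nearest differing neighbors on both sides are lower (ends never qualify).
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  mid <- 2:(k - 1L)
  keep <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][keep]
}

# Topographic prominence of each peak: height minus the higher of the two
# interval minima, each interval running to the nearest strictly higher
# sample on that side (or the signal end).
peak_prominence <- function(v, peaks) {
  vapply(peaks, function(p) {
    h <- v[p]
    left <- if (p > 1L) v[seq_len(p - 1L)] else numeric(0)
    right <- if (p < length(v)) v[(p + 1L):length(v)] else numeric(0)
    hi <- rev(left) > h
    lmin <- if (any(hi)) min(rev(left)[seq_len(which(hi)[1L] - 1L)]) else
      min(left, h)
    hi <- right > h
    rmin <- if (any(hi)) min(right[seq_len(which(hi)[1L] - 1L)]) else
      min(right, h)
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect calcium-transient peaks in a trace
#'
#' Local maxima are filtered by topographic prominence (as a fraction of the
#' trace's range) and then greedily accepted in order of decreasing
#' prominence subject to a minimum separation; ties are broken in favor of
#' the earlier peak.
#'
#' @param trace A [wg_trace()] of length >= 3, typically normalized
#'   (prominence is measured relative to the trace's own range either way).
#' @param min_prominence Minimum prominence as a fraction of
#'   `max(values) - min(values)`; default 0.1.
#' @param min_separation_s Minimum time between retained peaks, seconds;
#'   default 0 (no constraint).
#' @return An object of class `peak_series` with `peak_times_s` (seconds,
#'   `(index - 1) * frame_interval_s`), `prominences` (fraction of range),
#'   `indices`, and `frame_interval_s`. May be empty.
#' @export
detect_peaks <- function(trace, min_prominence = 0.1, min_separation_s = 0) {
  wg_check(inherits(trace, "wg_trace") && length(trace$values) >= 3L,
           "wavegraft_bad_trace", "need a wg_trace of length >= 3")
  v <- trace$values
  rng <- diff(range(v))
  peaks <- local_maxima(v)
  if (length(peaks) && rng > 0) {
    prom <- peak_prominence(v, peaks)
    keep <- prom >= min_prominence * rng
    peaks <- peaks[keep]; prom <- prom[keep]
  } else prom <- numeric(0)
  if (length(peaks) > 1L && min_separation_s > 0) {
    ord <- order(-prom, peaks) # decreasing prominence, earlier first on ties
    sel <- logical(length(peaks))
    t_s <- (peaks - 1) * trace$frame_interval_s
    for (i in ord) {
      if (!any(sel & abs(t_s - t_s[i]) < min_separation_s)) sel[i] <- TRUE
    }
    peaks <- peaks[sel]; prom <- prom[sel]
  }
  structure(list(
    peak_times_s = (peaks - 1) * trace$frame_interval_s,
    prominences = if (rng > 0) prom / rng else prom,
    indices = peaks,
    frame_interval_s = trace$frame_interval_s,
    source = trace$origin
  ), class = "peak_series")
}

event_times <- function(x) {
  if (inherits(x, "stimulus_train")) x$onset_times_s
  else if (inherits(x, "peak_series")) x$peak_times_s
  else if (is.numeric(x)) as.numeric(x)
  else wg_stop("wavegraft_bad_parameter",
               "expected a stimulus_train, peak_series, or numeric times")
}

#' Classify stimulus-locked transmission of waves to the graft
#'
#' A reference event at time `r` counts as transmitted when a graft peak
#' falls in the window `(r, r + window_s]`. Because the window must be
#' shorter than the smallest reference spacing, windows are disjoint and
#' each graft peak can serve at most one reference event.
#'
#' @param reference A [build_stimulus_train()], [detect_peaks()] result, or
#'   numeric vector of reference (monolayer or stimulus) event times in
#'   seconds.
#' @param graft A [detect_peaks()] result or numeric vector of graft peak
#'   times in seconds.
#' @param window_s Matching window in seconds; must be positive and smaller
#'   than the minimum reference spacing.
#' @return An object of class `sync_report`: `n_reference`, `n_transmitted`,
#'   `fraction` (exact), `percent` (half-up rounded to 0 decimals),
#'   `delays_s` (matched graft minus reference times, one per transmitted
#'   event), `window_s`, `coincidence_p` (1 when nothing was transmitted,
#'   otherwise `NA` until [coincidence_probability()] is run), `null_method`.
#' @examples
#' r <- 0:41
#' g <- seq(0, 38, by = 2) + 0.3
#' classify_synchronization(r, g, 0.8)$fraction
#' @export
classify_synchronization <- function(reference, graft, window_s) {
  ref <- sort(event_times(reference))
  gft <- sort(event_times(graft))
  wg_check(length(ref) >= 1L, "wavegraft_bad_parameter",
           "need at least one reference event")
  wg_check(is_scalar_num(window_s) && window_s > 0,
           "wavegraft_bad_parameter", "window_s must be positive")
  if (length(ref) > 1L)
    wg_check(window_s < min(diff(ref)), "wavegraft_overlapping_windows",
             "window_s must be smaller than the reference event spacing")
  delays <- rep(NA_real_, length(ref))
  if (length(gft)) {
    # first graft peak strictly after each reference event
    j <- findInterval(ref, gft) + 1L
    ok <- j <= length(gft)
    cand <- rep(NA_real_, length(ref))
    cand[ok] <- gft[j[ok]]
    hit <- !is.na(cand) & (cand - ref) <= window_s & (cand - ref) > 0
    delays[hit] <- cand[hit] - ref[hit]
  }
  n_trans <- sum(!is.na(delays))
  frac <- n_trans / length(ref)
  structure(list(
    n_reference = length(ref),
    n_transmitted = n_trans,
    fraction = frac,
    percent = round_half_up(100 * frac),
    delays_s = delays[!is.na(delays)],
    transmitted = !is.na(delays),
    reference_times_s = ref,
    graft_times_s = gft,
    window_s = window_s,
    coincidence_p = if (n_trans == 0L) 1 else NA_real_,
    null_method = NA_character_
  ), class = "sync_report")
}

#' @export
print.sync_report <- function(x, ...) {
  cat(sprintf("<sync_report> %d / %d reference waves transmitted (fraction %.3f, %d%%)\n",
              x$n_transmitted, x$n_reference, x$fraction, x$percent))
  if (x$n_transmitted > 0)
    cat(sprintf("  matched delays: mean %.3f s (window %.3f s)\n",
                mean(x$delays_s), x$window_s))
  if (!is.na(x$coincidence_p))
    cat(sprintf("  coincidence p (%s): %.3g\n", x$null_method, x$coincidence_p))
  invisible(x)
}

#' Coincidence probability of the observed synchronization under independence
#'
#' How likely is a graft cell firing independently of the monolayer to match
#' at least as many reference waves as observed? Two nulls are available:
#' an exact binomial tail with per-event hit probability
#' `p1 = min(1, window_s * graft_rate_hz)`, and a seeded Monte-Carlo null
#' that draws independent jittered periodic graft spike trains (period
#' `1/graft_rate_hz`, uniform phase) and reruns the matching rule.
#'
#' @param report A [classify_synchronization()] result.
#' @param graft_rate_hz Spontaneous graft firing rate, Hz (> 0).
#' @param method `"closed-form"` or `"monte-carlo"`.
#' @param n_draws Monte-Carlo sample size; default 10000.
#' @param seed Integer seed, required for `"monte-carlo"` (reproducibility
#'   contract).
#' @param jitter_s Gaussian jitter of Monte-Carlo spike times, seconds;
#'   default 10% of the spontaneous period.
#' @return An object of class `coincidence_test`: `p_value`, `method`,
#'   `p1`, `n_reference`, `n_transmitted`, and for Monte-Carlo `n_draws`
#'   and the binomial standard error `se`.
#' @export
coincidence_probability <- function(report, graft_rate_hz,
                                    method = c("closed-form", "monte-carlo"),
                                    n_draws = 10000, seed = NULL,
                                    jitter_s = NULL) {
  method <- match.arg(method)
  wg_check(inherits(report, "sync_report"), "wavegraft_bad_parameter",
           "report must come from classify_synchronization()")
  wg_check(is_scalar_num(graft_rate_hz) && graft_rate_hz > 0,
           "wavegraft_bad_parameter", "graft_rate_hz must be positive")
  w <- report$window_s
  n_ref <- report$n_reference
  n_trans <- report$n_transmitted
  p1 <- min(1, w * graft_rate_hz)
  if (method == "closed-form") {
    p <- stats::pbinom(n_trans - 1L, n_ref, p1, lower.tail = FALSE)
    out <- list(p_value = p, method = "closed-form", p1 = p1,
                n_reference = n_ref, n_transmitted = n_trans)
  } else {
    wg_check(!is.null(seed), "wavegraft_seed_required",
             "monte-carlo requires an explicit seed")
    period <- 1 / graft_rate_hz
    if (is.null(jitter_s)) jitter_s <- 0.1 * period
    ref <- report$reference_times_s
    t_lo <- min(ref) - period
    t_hi <- max(ref) + w + period
    n_spk <- ceiling((t_hi - t_lo) / period) + 1L
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    phase <- stats::runif(n_draws, 0, period)
    base <- outer(phase + t_lo, (seq_len(n_spk) - 1L) * period, "+")
    spikes <- base + stats::rnorm(length(base), 0, jitter_s)
    # disjoint windows: a spike hits reference i iff it lies in (ref_i, ref_i+w]
    ri <- findInterval(spikes, ref)
    hit <- ri >= 1L & (spikes - ref[pmax(ri, 1L)]) <= w &
      (spikes - ref[pmax(ri, 1L)]) > 0
    draw_id <- row(spikes)[hit]
    ref_id <- ri[hit]
    key <- unique((draw_id - 1) * n_ref + ref_id)
    K <- tabulate((key - 1) %/% n_ref + 1, nbins = n_draws)
    p <- mean(K >= n_trans)
    out <- list(p_value = p, method = "monte-carlo", p1 = p1,
                n_reference = n_ref, n_transmitted = n_trans,
                n_draws = n_draws, se = sqrt(p * (1 - p) / n_draws),
                jitter_s = jitter_s, seed = seed)
  }
  structure(out, class = "coincidence_test")
}

#' Estimate the number of cells a wave traverses from a distance
#'
#' `round(distance_um / cell_size_um)` with half-up rounding, floored at 1.
#'
#' @param distance_um Path length in micrometers (> 0).
#' @param cell_size_um Average spread cell size in the monolayer,
#'   micrometers; default 100.
#' @return Integer cell count (>= 1).
#' @examples
#' cells_from_distance(1000, 100) # 10
#' @export
cells_from_distance <- function(distance_um, cell_size_um = 100) {
  wg_check(is_scalar_num(distance_um) && distance_um > 0,
           "wavegraft_bad_parameter", "distance_um must be positive")
  wg_check(is_scalar_num(cell_size_um) && cell_size_um > 0,
           "wavegraft_bad_parameter", "cell_size_um must be positive")
  max(1L, as.integer(round_half_up(distance_um / cell_size_um)))
}

contact_time <- function(value_s, sigma_s, method, n_cells = NA_integer_,
                         n_waves = NA_integer_) {
  wg_check(is_scalar_num(value_s) && value_s > 0,
           "wavegraft_bad_parameter", "contact time must be positive")
  structure(list(value_s = value_s, sigma_s = sigma_s, method = method,
                 n_cells = n_cells, n_waves = n_waves),
            class = "contact_time")
}

contact_time_from_waves <- function(dt_s, n_cells, frame_interval_s, method) {
  wg_check(length(dt_s) >= 1L, "wavegraft_bad_parameter",
           "need at least one wave")
  wg_check(is_scalar_num(n_cells) && n_cells >= 1,
           "wavegraft_bad_parameter", "n_cells must be >= 1")
  m <- length(dt_s)
  value <- mean(dt_s) / n_cells
  sigma <- if (m > 1) stats::sd(dt_s) / (sqrt(m) * n_cells) else 0
  if (!is.null(frame_interval_s))
    # frame quantization floor: sd of a U(-dt/2, dt/2) timing error
    sigma <- max(sigma, frame_interval_s / (sqrt(12) * n_cells))
  contact_time(value, sigma, method, as.integer(n_cells), m)
}

#' Per-contact transmission time within the monolayer (cell-chain model)
#'
#' Models wave propagation between two monolayer regions as a chain of
#' `n_cells` cells in which intercellular contact traversal dominates
#' intracellular conduction: the per-contact time is the mean
#' region-to-region peak-time difference divided by `n_cells`. The
#' uncertainty is the standard error over waves, floored at the frame
#' quantization limit `frame_interval_s / (sqrt(12) * n_cells)`.
#'
#' @param peak_dt_s Per-wave peak-time differences between the wave
#'   initiation and termination regions, seconds.
#' @param n_cells Number of cells in the chain (>= 1); from direct counting
#'   or [cells_from_distance()].
#' @param frame_interval_s Seconds per frame, for the quantization floor;
#'   `NULL` to omit.
#' @param method Label recorded in the result: `"direct-count"` or
#'   `"distance-based"`.
#' @return An object of class `contact_time` with `value_s`, `sigma_s`,
#'   `method`, `n_cells`, `n_waves`.
#' @export
monolayer_contact_time <- function(peak_dt_s, n_cells,
                                   frame_interval_s = NULL,
                                   method = c("direct-count",
                                              "distance-based")) {
  method <- match.arg(method)
  contact_time_from_waves(peak_dt_s, n_cells, frame_interval_s, method)
}

#' Per-contact transmission time across the nascent graft contact
#'
#' The monolayer-to-graft delay crosses a single newly formed contact, so
#' the per-contact time is the mean matched delay itself.
#'
#' @param delays_s Per-wave monolayer-to-graft transmission delays, seconds
#'   (e.g. from [transmission_delay()] or a [classify_synchronization()]
#'   report).
#' @param frame_interval_s Seconds per frame for the quantization floor;
#'   `NULL` to omit.
#' @return An object of class `contact_time` with `method = "graft"`.
#' @export
graft_contact_time <- function(delays_s, frame_interval_s = NULL) {
  contact_time_from_waves(delays_s, 1L, frame_interval_s, "graft")
}

#' Graft/monolayer contact-efficiency ratio
#'
#' The efficiency of the mature monolayer contacts relative to the nascent
#' graft contact is the inverse ratio of per-contact transmission times;
#' reported as `graft.value_s / mono.value_s` with first-order uncertainty
#' propagation.
#'
#' @param graft,mono [contact_time] objects (graft and monolayer).
#' @return An object of class `efficiency_estimate`: `ratio`, `sigma`,
#'   `method` (the monolayer estimator's label).
#' @examples
#' g <- graft_contact_time(c(0.26, 0.27, 0.26))
#' m <- monolayer_contact_time(c(0.06, 0.061), n_cells = 10)
#' efficiency_ratio(g, m)$ratio
#' @export
efficiency_ratio <- function(graft, mono) {
  wg_check(inherits(graft, "contact_time") && inherits(mono, "contact_time"),
           "wavegraft_bad_parameter", "need two contact_time objects")
  ratio <- graft$value_s / mono$value_s
  sigma <- ratio * sqrt((graft$sigma_s / graft$value_s)^2 +
                          (mono$sigma_s / mono$value_s)^2)
  structure(list(ratio = ratio, sigma = sigma, method = mono$method,
                 graft = graft, mono = mono),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<efficiency_estimate> ratio %.1f +/- %.1f (monolayer estimator: %s)\n",
              x$ratio, x$sigma, x$method))
  invisible(x)
}
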