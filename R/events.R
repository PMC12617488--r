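#' Relative fluorescence change
#'
#' `dF/F = (F - F0) / F0` with `F0` the mode of the raw trace, estimated as
#' the center of the tallest histogram bin (Freedman-Diaconis bin width) — a
#' robust, deterministic mode estimator.
#'
#' @param f raw fluorescence trace.
#' @return dF/F trace with attribute `F0`.
#' @export
compute_dff <- function(f) {
  if (!all(is.finite(f))) stop("fluorescence trace must be finite")
  f0 <- trace_mode(f)
  if (f0 <= 0) stop("F0 <= 0: fluorescence appears offset-subtracted")
  out <- (f - f0) / f0
  attr(out, "F0") <- f0
  out
}

# histogram mode, Freedman-Diaconis width, center of the tallest bin
trace_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  iqr <- stats::IQR(x)
  w <- 2 * iqr / length(x)^(1 / 3)
  if (w <= 0) w <- diff(range(x)) / 30
  brk <- seq(min(x), max(x) + w, by = w)
  h <- hist(x, breaks = brk, plot = FALSE)
  h$mids[which.max(h$counts)]
}

# truncated-Gaussian smoothing kernel, sd in frames
gaussian_smooth <- function(x, sd_frames) {
  if (sd_frames <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_frames))
  k <- exp(-(seq(-half, half))^2 / (2 * sd_frames^2))
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

#' Cell-specific noise SD from resting trace segments
#'
#' The noise SD is the SD of the dF/F trace over the union of maximal
#' segments lasting at least `min_seg_s` seconds during which the inferred
#' spike rate stays below `max_rate_hz`. The continuous deconvolved samples
#' are converted to event weights by rounding to the nearest integer with a
#' minimum of 1 for any positive sample, and the rate is their moving 1-s
#' sum.
#'
#' @param dff dF/F trace.
#' @param spikes inferred-spike trace for the same cell.
#' @param frame_rate Hz.
#' @param max_rate_hz resting-rate ceiling (default 20 spikes/s).
#' @param min_seg_s minimum segment duration in seconds (default 1).
#' @return noise SD (scalar).
#' @export
estimate_noise_sd <- function(dff, spikes, frame_rate,
                              max_rate_hz = 20, min_seg_s = 1) {
  w <- ifelse(spikes > 0, pmax(1, round(spikes)), 0)
  win <- max(1L, round(frame_rate * 1))
  rate <- as.numeric(stats::filter(w, rep(1, win), sides = 2))
  rate[is.na(rate)] <- 0  # window truncated at the trace ends
  quiet <- rate < max_rate_hz
  r <- rle(quiet)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= round(min_seg_s * frame_rate)
  if (!any(keep))
    stop("no resting segment of >= ", min_seg_s,
         " s: cell too active to estimate noise")
  idx <- unlist(mapply(seq, starts[keep], ends[keep], SIMPLIFY = FALSE))
  if (length(idx) < 2) stop("resting segments too short to estimate noise")
  sd(dff[idx])
}

#' Detect calcium transients
#'
#' The dF/F trace is smoothed with a 100-ms Gaussian kernel; transients are
#' local maxima exceeding `thresh_mult` times the cell-specific noise SD.
#' A maximum closer than `min_sep_s` seconds to the previously retained
#' event is absorbed into it (merged, single count).
#'
#' @param dff dF/F trace.
#' @param sigma_cell noise SD from [estimate_noise_sd()].
#' @param frame_rate Hz.
#' @param thresh_mult detection threshold in noise SDs (default 3).
#' @param min_sep_s minimum separation between retained events (default 5 s).
#' @param smooth_sd_s Gaussian smoothing SD in seconds (default 0.1).
#' @return data.frame (frame, amplitude) of retained events.
#' @export
detect_transients <- function(dff, sigma_cell, frame_rate, thresh_mult = 3,
                              min_sep_s = 5, smooth_sd_s = 0.1) {
  stopifnot(sigma_cell >= 0)
  if (sigma_cell == 0 && any(dff != 0))
    stop("degenerate threshold: noise SD is 0 for a nonzero trace")
  x <- gaussian_smooth(as.numeric(dff), smooth_sd_s * frame_rate)
  n <- length(x)
  if (n < 3) return(data.frame(frame = integer(0), amplitude = numeric(0)))
  pk <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  pk <- pk[x[pk] > thresh_mult * sigma_cell]
  if (!length(pk)) return(data.frame(frame = integer(0), amplitude = numeric(0)))
  min_gap <- min_sep_s * frame_rate
  keep <- pk[1]
  for (p in pk[-1]) if (p - keep[length(keep)] >= min_gap) keep <- c(keep, p)
  data.frame(frame = keep, amplitude = x[keep])
}

#' Classify a cell's activity level
#'
#' Active: at least one detected calcium event per minute. Sufficiently
#' active (the stricter filter used for event-session analyses): mean
#' inferred spike rate strictly above 1 event/s.
#'
#' @param events output of [detect_transients()].
#' @param duration_s session duration in seconds.
#' @param spikes inferred-spike trace for the cell.
#' @param frame_rate Hz (unused beyond documentation; rates are per second
#'   of `duration_s`).
#' @return list with `n_events`, `events_per_min`, `is_active`,
#'   `mean_rate_hz`, `is_sufficiently_active`.
#' @export
classify_activity <- function(events, duration_s, spikes, frame_rate = NULL) {
  stopifnot(duration_s > 0)
  epm <- nrow(events) / (duration_s / 60)
  rate <- sum(spikes) / duration_s
  list(n_events = nrow(events), events_per_min = epm,
       is_active = epm >= 1, mean_rate_hz = rate,
       is_sufficiently_active = rate > 1)
}

#' Per-cell event detection and activity table for a session
#'
#' Runs [compute_dff()], [estimate_noise_sd()], [detect_transients()] and
#' [classify_activity()] over all cells. Cells whose noise SD cannot be
#' estimated (no resting segment) are marked with `NA` noise and counted as
#' active by their inferred rate alone.
#'
#' @param s a `corridor_session`.
#' @param ... passed to [detect_transients()].
#' @return data.frame, one row per cell.
#' @export
activity_table <- function(s, ...) {
  dur <- n_frames(s) / s$frame_rate
  out <- lapply(seq_len(n_cells(s)), function(ci) {
    f <- s$fluorescence[ci, ]
    sp <- s$spikes[ci, ]
    res <- tryCatch({
      dff <- compute_dff(f)
      sig <- estimate_noise_sd(dff, sp, s$frame_rate)
      ev <- detect_transients(dff, sig, s$frame_rate, ...)
      st <- classify_activity(ev, dur, sp)
      data.frame(cell = ci, noise_sd = sig, n_events = st$n_events,
                 events_per_min = st$events_per_min,
                 is_active = st$is_active, mean_rate_hz = st$mean_rate_hz,
                 is_sufficiently_active = st$is_sufficiently_active)
    }, error = function(e) {
      rate <- sum(sp) / dur
      data.frame(cell = ci, noise_sd = NA_real_, n_events = NA_integer_,
                 events_per_min = NA_real_, is_active = rate > 1 / 60,
                 mean_rate_hz = rate, is_sufficiently_active = rate > 1)
    })
    res
  })
  do.call(rbind, out)
}
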