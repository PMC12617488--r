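#' Score a single lap
#'
#' Go/no-go rule: an R lap is correct iff it contains at least one lick event
#' (rising edge of the lick signal) inside the reward zone; a U lap is
#' correct iff it contains none. Only correct R laps are rewarded.
#'
#' @param lap_row one row of [segment_laps()] output.
#' @param s the `corridor_session` the row was segmented from.
#' @param rz_fraction reward-zone fraction of the corridor (default 0.1).
#' @return list with `correct` and `rewarded` logicals.
#' @export
score_lap <- function(lap_row, s, rz_fraction = 0.1) {
  if (lap_row$n_frames < 1) stop("lap with no frames")
  fr <- lap_row$first_frame:lap_row$last_frame
  rz_start <- s$corridor_length * (1 - rz_fraction)
  n_rz <- sum(lick_onsets(s$lick[fr]) & s$position[fr] >= rz_start,
              na.rm = TRUE)
  correct <- if (lap_row$corridor == "R") n_rz >= 1 else n_rz == 0
  list(correct = correct, rewarded = lap_row$corridor == "R" && correct)
}

#' Moving-window performance and LOW/MED/HIGH epoch labels
#'
#' Performance at lap k is the trailing fraction of correct laps over the
#' last `min(window, k)` laps. Labels: LOW iff perf < 0.65, HIGH iff
#' perf > 0.84, otherwise MED (strict inequalities; the boundary values map
#' to MED). The criterion lap is the first lap at which the trailing
#' `window`-lap window holds at least `ceiling(0.9 * window)` correct laps
#' (36 of 40 at the default window).
#'
#' @param correct logical per-lap correctness flags.
#' @param window moving-average window in laps (default 40).
#' @param low,high epoch thresholds (defaults 0.65 and 0.84).
#' @return data.frame (lap, perf, label) with attribute `criterion_lap`
#'   (0-based lap index, or `NA` if never reached).
#' @export
performance_series <- function(correct, window = 40,
                               low = 0.65, high = 0.84) {
  stopifnot(length(correct) >= 1, low < high)
  n <- length(correct)
  cs <- cumsum(correct)
  k <- seq_len(n)
  lo <- pmax(k - window, 0L)
  frac <- (cs - c(0, cs)[lo + 1L]) / pmin(k, window)
  label <- ifelse(frac < low, "LOW", ifelse(frac > high, "HIGH", "MED"))
  out <- data.frame(lap = k - 1L, perf = frac, label = label)
  need <- ceiling(0.9 * window)
  full <- which(k >= window &
                  (cs - c(0, cs)[pmax(k - window, 0L) + 1L]) >= need)
  attr(out, "criterion_lap") <- if (length(full)) full[1] - 1L else NA_integer_
  out
}

#' Select a contiguous epoch of laps with a given performance label
#'
#' Finds the longest run of consecutive laps whose moving-window performance
#' carries the requested label, requiring at least `min_laps` laps.
#'
#' @param perf output of [performance_series()].
#' @param label `"LOW"`, `"MED"` or `"HIGH"`.
#' @param min_laps minimum epoch length (default 30).
#' @return integer vector of 0-based lap indices, or `NULL` when no epoch of
#'   the required length exists.
#' @export
find_epoch <- function(perf, label, min_laps = 30) {
  hit <- perf$label == label
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_laps)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]
  perf$lap[starts[best]:ends[best]]
}

#' Spatially binned lick rate and running speed per corridor
#'
#' Lick events (rising edges) and occupancy time are accumulated per spatial
#' bin and corridor over the selected laps: per-bin lick rate is
#' events / occupancy seconds, per-bin speed is the occupancy-weighted mean
#' frame speed. Bins with zero occupancy are `NA`, never zero-filled. Zone
#' aggregates (RZ/PZ/CZ and the rewarded/unrewarded PZ pair) are means over
#' the behavioral zone bins.
#'
#' @param s a `corridor_session`.
#' @param laps optional 0-based lap indices to restrict to.
#' @return list with `bins` (data.frame corridor, bin, lick_rate, speed,
#'   occupancy_s) and `zones` (data.frame corridor, zone, lick_rate, speed).
#' @export
bin_behavior <- function(s, laps = NULL) {
  ng <- s$corridor != GRAY
  if (!is.null(laps)) ng <- ng & s$lap %in% laps
  if (!any(ng)) stop("no corridor frames in the selected laps")
  dt <- 1 / s$frame_rate
  b <- bin_position(s$position, s$corridor_length, s$n_bins)
  on <- lick_onsets(s$lick)
  zb <- zone_bins("behavior")
  rows <- list(); zrows <- list()
  for (cc in setdiff(unique(s$corridor), GRAY)) {
    m <- ng & s$corridor == cc
    f <- factor(b[m], levels = 0:(s$n_bins - 1))
    occ <- tabulate(f, nbins = s$n_bins) * dt
    licks <- vapply(split(as.numeric(on[m]), f), sum, numeric(1))
    spd <- vapply(split(s$speed[m], f), function(x)
      if (length(x)) mean(x) else NA_real_, numeric(1))
    lr <- ifelse(occ > 0, licks / occ, NA_real_)
    spd[occ == 0] <- NA_real_
    rows[[cc]] <- data.frame(corridor = cc, bin = 0:(s$n_bins - 1),
                             lick_rate = lr, speed = spd, occupancy_s = occ)
    for (zn in names(zb)) {
      zi <- zb[[zn]] + 1L
      zrows[[paste(cc, zn)]] <- data.frame(
        corridor = cc, zone = zn,
        lick_rate = mean(lr[zi], na.rm = TRUE),
        speed = mean(spd[zi], na.rm = TRUE))
    }
  }
  list(bins = do.call(rbind, c(rows, make.row.names = FALSE)),
       zones = do.call(rbind, c(zrows, make.row.names = FALSE)))
}

.zone_value <- function(binned, corridor, zone, quantity) {
  z <- binned$zones
  v <- z[[quantity]][z$corridor == corridor & z$zone == zone]
  if (length(v) != 1) NA_real_ else v
}

#' Intracorridor lick or speed index
#'
#' `(xPZ - xCZ) / (xPZ + xCZ)` computed within one corridor, where x is the
#' lick rate or the mean speed in the prezone (PZ) and control zone (CZ).
#' Positive values indicate anticipatory elevation approaching the reward
#' zone. Undefined (`NA`) when `xPZ + xCZ` is zero.
#'
#' @param binned output of [bin_behavior()].
#' @param corridor `"U"` or `"R"`.
#' @param quantity `"lick_rate"` or `"speed"`.
#' @return index in `[-1, 1]`, or `NA`.
#' @export
lick_speed_index <- function(binned, corridor,
                             quantity = c("lick_rate", "speed")) {
  quantity <- match.arg(quantity)
  pz <- .zone_value(binned, corridor, "pz", quantity)
  cz <- .zone_value(binned, corridor, "cz", quantity)
  if (!is.finite(pz + cz) || pz + cz == 0) return(NA_real_)
  (pz - cz) / (pz + cz)
}

#' Intercorridor lick or speed selectivity
#'
#' `(xPZrew - xPZunrew) / (xPZrew + xPZunrew)` where the two terms are the
#' lick rate or mean speed in the prezone of the rewarded (R) and unrewarded
#' (U) corridors. Positive values indicate discrimination in favor of the
#' rewarded corridor. Undefined (`NA`) when the denominator is zero.
#'
#' @param binned output of [bin_behavior()].
#' @param quantity `"lick_rate"` or `"speed"`.
#' @return selectivity in `[-1, 1]`, or `NA`.
#' @export
intercorridor_selectivity <- function(binned,
                                      quantity = c("lick_rate", "speed")) {
  quantity <- match.arg(quantity)
  r <- .zone_value(binned, "R", "pz", quantity)
  u <- .zone_value(binned, "U", "pz", quantity)
  if (!is.finite(r + u) || r + u == 0) return(NA_real_)
  (r - u) / (r + u)
}
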