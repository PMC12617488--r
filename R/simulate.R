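#' Configuration for the synthetic session generator
#'
#' Defines a CA1-like population navigating the virtual contextual go/no-go
#' task: 106-cm corridors traversed at ~20 cm/s, a pseudorandom balanced U/R
#' schedule in blocks of 4, gray timeout zones between laps (0.5 s after
#' correct laps, a ~2.5-s run-through after errors), Gaussian place fields
#' tiling the track with reward-zone over-representation, a multiplicative
#' R-corridor gain carrying corridor selectivity, Poisson spiking, and
#' exponential-kernel (tau = 0.8 s) fluorescence with additive Gaussian
#' noise. Scripted events: an abrupt remap at a Switch lap or gradual field
#' drift from a Reversal lap.
#'
#' @param n_cells number of cells (default 200).
#' @param n_laps number of corridor laps (default 60).
#' @param frame_rate imaging rate, Hz (default 30).
#' @param corridor_length cm (default 106).
#' @param n_bins spatial bins (default 50).
#' @param speed_base baseline running speed, cm/s (default 20).
#' @param speed_sd per-frame speed jitter SD, cm/s (default 2).
#' @param speed_min floor on instantaneous speed, cm/s (default 6, above the
#'   5 cm/s running threshold so simulated laps are fully analyzable).
#' @param pz_slow_factor multiplicative slowing of speed in the anticipation
#'   zone (PZ + RZ) of the R corridor during HIGH-stage laps (default 0.6).
#' @param stage behavioral stage for all laps, `"LOW"` or `"HIGH"`
#'   (default `"HIGH"`); `stage_change_lap` scripts a LOW-then-HIGH session.
#' @param stage_change_lap first HIGH lap, or `NA` for a single-stage session.
#' @param lick_base_hz baseline lick rate anywhere on the track (default 0.2).
#' @param lick_rz_hz elevated anticipatory lick rate in PZ + RZ (default 4);
#'   applied in both corridors during LOW laps, only in R during HIGH laps.
#' @param frac_tuned fraction of cells with a place field (default 0.5).
#' @param field_sigma place-field width SD, cm (default 8).
#' @param field_amp_hz field peak amplitude above baseline, events/s
#'   (default 12, chosen so that single-lap population vectors of the same
#'   corridor correlate at the ~0.6-0.7 level seen in CA1 event data).
#' @param baseline_hz out-of-field rate of tuned cells, events/s
#'   (default 0.2).
#' @param untuned_hz homogeneous rate of untuned cells, events/s (default 1).
#' @param rz_overrep probability that a field center is drawn inside the
#'   reward zone rather than uniformly over the track (default 0.2).
#' @param gain corridor gain g >= 0 multiplying the field amplitude in the R
#'   corridor; scalar or per-cell vector (default 1, no selectivity). The
#'   zero-baseline whole-corridor selectivity implied is (g-1)/(g+1).
#' @param field_corridor `"both"`, `"U"` or `"R"`; scalar or per-cell vector.
#'   Restricts the field to one corridor (disjoint context codes).
#' @param tau_s calcium indicator decay time constant, s (default 0.8).
#' @param fluor_base,fluor_amp,fluor_noise_sd fluorescence baseline,
#'   per-event transient amplitude, and additive noise SD (arbitrary units;
#'   defaults 1, 0.3, 0.05).
#' @param gray_correct_s,gray_error_s gray timeout duration after correct and
#'   error laps, s (defaults 0.5 and 2.5).
#' @param event_type `"none"`, `"switch"` or `"reversal"`.
#' @param event_lap 0-based lap at which the event takes effect.
#' @param remap_frac fraction of cells that resample field center and gain at
#'   a Switch (default 0).
#' @param drift_sd_cm per-lap Gaussian drift SD of field centers after a
#'   Reversal, cm (default 0).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 200, n_laps = 60, frame_rate = 30,
                       corridor_length = 106, n_bins = 50,
                       speed_base = 20, speed_sd = 2, speed_min = 6,
                       pz_slow_factor = 0.6,
                       stage = c("HIGH", "LOW"), stage_change_lap = NA,
                       lick_base_hz = 0.2, lick_rz_hz = 4,
                       frac_tuned = 0.5, field_sigma = 8, field_amp_hz = 12,
                       baseline_hz = 0.2, untuned_hz = 1, rz_overrep = 0.2,
                       gain = 1, field_corridor = "both",
                       tau_s = 0.8, fluor_base = 1, fluor_amp = 0.3,
                       fluor_noise_sd = 0.05,
                       gray_correct_s = 0.5, gray_error_s = 2.5,
                       event_type = c("none", "switch", "reversal"),
                       event_lap = NA, remap_frac = 0, drift_sd_cm = 0) {
  stage <- match.arg(stage)
  event_type <- match.arg(event_type)
  cfg <- as.list(environment())
  stopifnot(n_cells >= 0, n_laps >= 1, frame_rate > 0, tau_s > 0,
            frac_tuned >= 0, frac_tuned <= 1, remap_frac >= 0,
            remap_frac <= 1, all(gain >= 0), baseline_hz >= 0,
            field_amp_hz >= 0, untuned_hz >= 0, drift_sd_cm >= 0)
  if (speed_base <= 0) stop("speed_base must be positive")
  if (event_type != "none" &&
      (is.na(event_lap) || event_lap < 1 || event_lap >= n_laps))
    stop("event lap out of range")
  class(cfg) <- "sim_config"
  cfg
}

# derive sub-seeds that stay well inside 32-bit integer range
derive_seed <- function(seed, k) as.integer((as.numeric(seed) + 77777 * k) %% 2147483647)

# anticipation zone (PZ + RZ) start and RZ start, in cm
pz_start_cm <- function(cfg) cfg$corridor_length * 0.8
rz_start_cm <- function(cfg) cfg$corridor_length * 0.9

#' Per-lap behavioral stage labels
#' @keywords internal
lap_stages <- function(cfg) {
  st <- rep(cfg$stage, cfg$n_laps)
  if (!is.na(cfg$stage_change_lap)) {
    st <- rep("LOW", cfg$n_laps)
    st[seq_len(cfg$n_laps) - 1 >= cfg$stage_change_lap] <- "HIGH"
  }
  st
}

#' Simulate the behavioral trajectory
#'
#' Corridor laps traverse 0 to `corridor_length` monotonically at a jittered
#' speed (with anticipatory slowing before the reward zone of the R corridor
#' on HIGH-stage laps), separated by gray timeout interludes whose duration
#' depends on the previous lap's correctness. The corridor schedule is
#' pseudorandom and balanced in blocks of 4 (2 U + 2 R, shuffled).
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @param correct optional per-lap correctness flags driving gray durations;
#'   when `NULL` all interludes use the correct-lap duration.
#' @return data.frame (time, position, corridor, lap, speed) with attributes
#'   `schedule` (corridor per lap) and `stage` (per-lap stage labels).
#' @export
simulate_trajectory <- function(cfg, seed, correct = NULL) {
  set.seed(seed)
  n_blocks <- ceiling(cfg$n_laps / 4)
  sched <- unlist(lapply(seq_len(n_blocks),
                         function(i) sample(c("U", "U", "R", "R"))))
  sched <- sched[seq_len(cfg$n_laps)]
  stage <- lap_stages(cfg)
  dt <- 1 / cfg$frame_rate
  slow_from <- pz_start_cm(cfg)
  tm <- pos <- spd <- numeric(0); cor_id <- character(0); lap <- integer(0)
  t0 <- 0
  for (l in seq_len(cfg$n_laps)) {
    p <- 0; lp <- ls <- numeric(0)
    while (p < cfg$corridor_length) {
      base <- cfg$speed_base
      if (sched[l] == "R" && stage[l] == "HIGH" && p >= slow_from)
        base <- base * cfg$pz_slow_factor
      v <- max(cfg$speed_min, base + rnorm(1, 0, cfg$speed_sd))
      lp <- c(lp, p); ls <- c(ls, v)
      p <- p + v * dt
    }
    nf <- length(lp)
    tm <- c(tm, t0 + dt * seq_len(nf)); t0 <- t0 + dt * nf
    pos <- c(pos, lp); spd <- c(spd, ls)
    cor_id <- c(cor_id, rep(sched[l], nf)); lap <- c(lap, rep(l - 1L, nf))
    ok <- if (is.null(correct)) TRUE else isTRUE(correct[l])
    gdur <- if (ok) cfg$gray_correct_s else cfg$gray_error_s
    ng <- max(1L, round(gdur * cfg$frame_rate))
    tm <- c(tm, t0 + dt * seq_len(ng)); t0 <- t0 + dt * ng
    pos <- c(pos, rep(NA_real_, ng)); spd <- c(spd, rep(cfg$speed_base, ng))
    cor_id <- c(cor_id, rep(GRAY, ng)); lap <- c(lap, rep(l - 1L, ng))
  }
  out <- data.frame(time = tm, position = pos, corridor = cor_id,
                    lap = lap, speed = spd)
  attr(out, "schedule") <- sched
  attr(out, "stage") <- stage
  out
}

#' Simulate licking and rewards on a trajectory
#'
#' Licks are an inhomogeneous Bernoulli process per frame: a low baseline
#' rate everywhere plus an elevated anticipatory rate in the PZ + RZ region —
#' in both corridors on LOW-stage laps, only in the R corridor on HIGH-stage
#' laps. A reward is issued at the first lick inside the reward zone of an R
#' lap.
#'
#' @param cfg a [sim_config()].
#' @param traj output of [simulate_trajectory()].
#' @param seed integer RNG seed.
#' @return list with logical per-frame `lick` and `reward`.
#' @export
simulate_licks <- function(cfg, traj, seed) {
  set.seed(seed)
  stage <- attr(traj, "stage")
  ng <- traj$corridor != GRAY
  rate <- rep(0, nrow(traj))
  in_az <- ng & traj$position >= pz_start_cm(cfg)
  lap_stage <- stage[traj$lap + 1L]
  elev <- in_az & (lap_stage == "LOW" | traj$corridor == "R")
  rate[ng] <- cfg$lick_base_hz
  rate[which(elev)] <- cfg$lick_rz_hz
  lick <- rep(FALSE, nrow(traj))
  # draw only on corridor frames so the pattern is invariant to gray lengths
  lick[ng] <- runif(sum(ng)) < rate[ng] / cfg$frame_rate
  reward <- rep(FALSE, nrow(traj))
  rzs <- rz_start_cm(cfg)
  on <- lick_onsets(lick)
  for (l in unique(traj$lap[ng & traj$corridor == "R"])) {
    fr <- which(traj$lap == l & traj$corridor == "R" & on &
                  traj$position >= rzs)
    if (length(fr)) reward[fr[1]] <- TRUE
  }
  list(lick = lick, reward = reward)
}

# per-cell tuning parameters, with event-dependent post variants
draw_cell_params <- function(cfg) {
  n <- cfg$n_cells
  tuned <- runif(n) < cfg$frac_tuned
  draw_centers <- function(n) {
    rz <- runif(n) < cfg$rz_overrep
    ifelse(rz, runif(n, rz_start_cm(cfg), cfg$corridor_length),
           runif(n, 0, cfg$corridor_length))
  }
  centers <- draw_centers(n)
  gain <- rep_len(cfg$gain, n)
  fc <- rep_len(cfg$field_corridor, n)
  remapped <- rep(FALSE, n)
  centers2 <- centers; gain2 <- gain
  if (cfg$event_type == "switch" && cfg$remap_frac > 0) {
    remapped <- runif(n) < cfg$remap_frac
    new_c <- draw_centers(n)
    new_g <- rep_len(cfg$gain, n)
    centers2[remapped] <- new_c[remapped]
    gain2[remapped] <- new_g[remapped]
  }
  list(tuned = tuned, centers = centers, gain = gain, field_corridor = fc,
       remapped = remapped, centers_post = centers2, gain_post = gain2)
}

#' Simulate spiking and fluorescence for a population
#'
#' Each tuned cell fires as an inhomogeneous Poisson process with rate
#' baseline + amplitude * Gaussian(position; center, sigma), the amplitude
#' multiplied by the corridor gain in R; untuned cells are homogeneous
#' Poisson. Fluorescence is the exponential-kernel (tau) convolution of the
#' spikes plus a baseline offset and Gaussian noise. Switch events abruptly
#' resample the fields of a fraction of cells from the event lap on;
#' Reversal events add per-lap Gaussian drift to field centers.
#'
#' @param cfg a [sim_config()].
#' @param traj output of [simulate_trajectory()].
#' @param seed integer RNG seed.
#' @return list with `spikes` and `fluorescence` (cells x frames) and a
#'   `truth` data.frame of per-cell ground-truth parameters.
#' @export
simulate_cells <- function(cfg, traj, seed) {
  set.seed(seed)
  n <- cfg$n_cells
  nf <- nrow(traj)
  pars <- draw_cell_params(cfg)
  # per-lap field-center offsets (reversal drift)
  drift <- matrix(0, n, cfg$n_laps)
  if (cfg$event_type == "reversal" && cfg$drift_sd_cm > 0) {
    post <- which(seq_len(cfg$n_laps) - 1 >= cfg$event_lap)
    if (length(post)) {
      steps <- matrix(rnorm(n * length(post), 0, cfg$drift_sd_cm),
                      n, length(post))
      drift[, post] <- t(apply(steps, 1, cumsum))
    }
  }
  rate <- matrix(cfg$baseline_hz, n, nf)
  if (n > 0) rate[!pars$tuned, ] <- cfg$untuned_hz
  ng <- which(traj$corridor != GRAY)
  pos <- traj$position[ng]; lapv <- traj$lap[ng]
  in_r <- traj$corridor[ng] == "R"
  post_ev <- if (cfg$event_type == "switch") lapv >= cfg$event_lap
             else rep(FALSE, length(ng))
  for (ci in which(pars$tuned)) {
    ctr <- ifelse(post_ev, pars$centers_post[ci], pars$centers[ci]) +
      drift[ci, lapv + 1L]
    g <- ifelse(post_ev, pars$gain_post[ci], pars$gain[ci])
    amp <- cfg$field_amp_hz * ifelse(in_r, g, 1)
    fc <- pars$field_corridor[ci]
    if (fc == "U") amp[in_r] <- 0
    if (fc == "R") amp[!in_r] <- 0
    rate[ci, ng] <- cfg$baseline_hz +
      amp * exp(-(pos - ctr)^2 / (2 * cfg$field_sigma^2))
  }
  spikes <- matrix(rpois(n * nf, rate / cfg$frame_rate), n, nf)
  decay <- exp(-1 / (cfg$tau_s * cfg$frame_rate))
  fluor <- matrix(0, n, nf)
  for (ci in seq_len(n)) {
    conv <- stats::filter(spikes[ci, ], decay, method = "recursive")
    fluor[ci, ] <- cfg$fluor_base + cfg$fluor_amp * as.numeric(conv) +
      rnorm(nf, 0, cfg$fluor_noise_sd)
  }
  w <- cfg$corridor_length / cfg$n_bins
  sel_of_gain <- function(g, fc) {
    s <- (g - 1) / (g + 1)
    s[fc == "U"] <- -1; s[fc == "R"] <- 1
    s
  }
  truth <- data.frame(
    cell = seq_len(n), is_tuned = pars$tuned,
    sigma_cm = rep(cfg$field_sigma, n),
    center_cm = pars$centers,
    center_bin = pmin(floor(pars$centers / w), cfg$n_bins - 1),
    gain = pars$gain, field_corridor = pars$field_corridor,
    true_selectivity = ifelse(pars$tuned,
                              sel_of_gain(pars$gain, pars$field_corridor), 0),
    remapped = pars$remapped,
    center_post_cm = pars$centers_post, gain_post = pars$gain_post)
  list(spikes = spikes, fluorescence = fluor, truth = truth)
}

#' Simulate a complete session with ground truth
#'
#' Deterministic given `(cfg, seed)`. The trajectory is generated, licks are
#' drawn and laps scored, then the trajectory is regenerated from the same
#' seed with gray-zone durations conditioned on lap correctness, and the
#' population activity is simulated on the final trajectory.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed driving all randomness.
#' @return list with `session` (a `corridor_session`) and `truth` (list with
#'   per-cell data.frame `cells`, per-lap data.frame `laps`, the `config` and
#'   `seed`).
#' @export
simulate_session <- function(cfg, seed) {
  traj0 <- simulate_trajectory(cfg, seed)
  lk0 <- simulate_licks(cfg, traj0, derive_seed(seed, 1))
  rzs <- rz_start_cm(cfg)
  sched <- attr(traj0, "schedule")
  on0 <- lick_onsets(lk0$lick)
  rz_lick <- vapply(seq_len(cfg$n_laps) - 1L, function(l)
    any(on0 & traj0$lap == l & traj0$corridor != GRAY &
          traj0$position >= rzs), logical(1))
  correct <- ifelse(sched == "R", rz_lick, !rz_lick)
  traj <- simulate_trajectory(cfg, seed, correct = correct)
  lk <- simulate_licks(cfg, traj, derive_seed(seed, 1))
  act <- simulate_cells(cfg, traj, derive_seed(seed, 2))
  sess <- new_session(traj$time, traj$position, traj$corridor, traj$lap,
                      traj$speed, lk$lick, lk$reward,
                      act$fluorescence, act$spikes,
                      frame_rate = cfg$frame_rate,
                      corridor_length = cfg$corridor_length,
                      n_bins = cfg$n_bins)
  laps <- data.frame(lap_index = seq_len(cfg$n_laps) - 1L,
                     corridor = sched, stage = attr(traj, "stage"),
                     correct = correct,
                     rewarded = sched == "R" & correct)
  list(session = sess,
       truth = list(cells = act$truth, laps = laps, config = cfg,
                    seed = seed))
}

#' Switch-event variant of a configuration
#'
#' From the event lap on, a configured fraction of cells abruptly resamples
#' its field center and corridor gain (global remapping of part of the
#' population), emulating an uncued context switch.
#'
#' @param cfg a [sim_config()].
#' @param event_lap 0-based lap of the switch.
#' @param remap_frac fraction of cells that remap.
#' @return modified `sim_config`.
#' @export
inject_switch <- function(cfg, event_lap, remap_frac = 0.5) {
  if (is.na(event_lap) || event_lap < 1 || event_lap >= cfg$n_laps)
    stop("event lap out of range")
  cfg$event_type <- "switch"
  cfg$event_lap <- event_lap
  cfg$remap_frac <- remap_frac
  cfg
}

#' Reversal-event variant of a configuration
#'
#' From the event lap on, field centers drift lap by lap with Gaussian steps
#' of the configured SD, emulating the gradual reorganization seen after a
#' reward-contingency reversal.
#'
#' @param cfg a [sim_config()].
#' @param event_lap 0-based lap of the reversal.
#' @param drift_sd_cm per-lap drift SD in cm.
#' @return modified `sim_config`.
#' @export
inject_reversal_drift <- function(cfg, event_lap, drift_sd_cm = 2) {
  if (is.na(event_lap) || event_lap < 1 || event_lap >= cfg$n_laps)
    stop("event lap out of range")
  cfg$event_type <- "reversal"
  cfg$event_lap <- event_lap
  cfg$drift_sd_cm <- drift_sd_cm
  cfg
}
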