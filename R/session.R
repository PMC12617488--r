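#' @importFrom stats sd cor median rnorm runif rpois rbinom quantile setNames
#' @importFrom utils head tail
NULL

GRAY <- "GRAY"

#' Construct an aligned imaging session
#'
#' A session holds per-frame behavior (time, position along the corridor,
#' corridor identity, lap index, running speed, licks, rewards) aligned to
#' per-frame neural activity (raw fluorescence and deconvolved inferred
#' spikes, cells x frames). Position is measured in cm from corridor entry and
#' is undefined (`NA`) on gray timeout-zone frames; analyses must always mask
#' gray frames rather than interpret the sentinel.
#'
#' @param time numeric, frame times in seconds.
#' @param position numeric, cm in `[0, corridor_length]`; `NA` on gray frames.
#' @param corridor character per frame, e.g. `"U"`, `"R"`, `"GRAY"`.
#' @param lap integer per frame, 0-based, non-decreasing; gray frames carry
#'   the index of the preceding lap.
#' @param speed numeric, cm/s, non-negative.
#' @param lick,reward logical per frame.
#' @param fluorescence,spikes numeric matrices, cells x frames; spikes are
#'   non-negative deconvolved activity.
#' @param frame_rate Hz (default 30).
#' @param corridor_length cm (default 106).
#' @param n_bins number of spatial bins (default 50).
#' @return an object of class `corridor_session`.
#' @export
new_session <- function(time, position, corridor, lap, speed, lick, reward,
                        fluorescence, spikes, frame_rate = 30,
                        corridor_length = 106, n_bins = 50) {
  s <- structure(list(
    time = as.numeric(time), position = as.numeric(position),
    corridor = as.character(corridor), lap = as.integer(lap),
    speed = as.numeric(speed), lick = as.logical(lick),
    reward = as.logical(reward),
    fluorescence = matrix(as.numeric(fluorescence), nrow(fluorescence),
                          ncol(fluorescence)),
    spikes = matrix(as.numeric(spikes), nrow(spikes), ncol(spikes)),
    frame_rate = as.numeric(frame_rate),
    corridor_length = as.numeric(corridor_length),
    n_bins = as.integer(n_bins)), class = "corridor_session")
  validate_session(s)
  s
}

#' Validate a session's invariants
#'
#' Checks that all per-frame sequences share one length, positions lie in
#' `[0, corridor_length]` on non-gray frames, lap indices are non-decreasing,
#' speeds and inferred spikes are non-negative and the frame rate is positive.
#'
#' @param s a `corridor_session`.
#' @return `s`, invisibly; errors describe the violated invariant.
#' @export
validate_session <- function(s) {
  n <- length(s$time)
  lens <- c(position = length(s$position), corridor = length(s$corridor),
            lap = length(s$lap), speed = length(s$speed),
            lick = length(s$lick), reward = length(s$reward),
            fluorescence = ncol(s$fluorescence), spikes = ncol(s$spikes))
  if (any(lens != n))
    stop("length mismatch: time has ", n, " frames but ",
         paste(sprintf("%s=%d", names(lens)[lens != n], lens[lens != n]),
               collapse = ", "))
  ng <- s$corridor != GRAY
  if (anyNA(s$position[ng]) ||
      any(s$position[ng] < 0 | s$position[ng] > s$corridor_length))
    stop("position out of [0, corridor_length] on non-gray frames")
  if (is.unsorted(s$lap)) stop("lap_index must be non-decreasing")
  if (any(s$speed < 0, na.rm = TRUE)) stop("speed must be >= 0")
  if (nrow(s$spikes) > 0 && any(s$spikes < 0)) stop("inferred spikes must be >= 0")
  if (!isTRUE(s$frame_rate > 0)) stop("frame_rate must be > 0")
  if (s$n_bins < 1) stop("n_bins must be >= 1")
  invisible(s)
}

n_frames <- function(s) length(s$time)
n_cells <- function(s) nrow(s$spikes)

.session_files <- c("behavior.csv", "fluorescence.csv", "spikes.csv",
                    "attributes.yaml")

# doubles are serialized at 17 significant digits so that text round trips
# are bit-exact
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

.write_matrix_csv <- function(m, path) {
  ch <- matrix(.fmt_num(m), nrow(m), ncol(m))
  data.table::fwrite(data.table::as.data.table(ch), path)
}

.read_matrix_csv <- function(path, n_frames) {
  d <- data.table::fread(path, colClasses = "character")
  if (nrow(d) == 0) return(matrix(numeric(0), 0, n_frames))
  m <- matrix(as.numeric(as.matrix(d)), nrow(d), ncol(d))
  dimnames(m) <- NULL
  m
}

#' Save a session to a directory of CSV tables plus a YAML attribute file
#'
#' Writes `behavior.csv` (per-frame columns), `fluorescence.csv` and
#' `spikes.csv` (cells x frames, one row per cell) and `attributes.yaml`
#' (frame rate, geometry). Doubles are written in shortest round-trippable
#' form, so [load_session()] reproduces every array bit-identically.
#'
#' @param s a `corridor_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  beh <- data.table::data.table(
    time = .fmt_num(s$time), position = .fmt_num(s$position),
    corridor = s$corridor, lap = s$lap, speed = .fmt_num(s$speed),
    lick = as.integer(s$lick), reward = as.integer(s$reward))
  data.table::fwrite(beh, file.path(path, "behavior.csv"))
  .write_matrix_csv(s$fluorescence, file.path(path, "fluorescence.csv"))
  .write_matrix_csv(s$spikes, file.path(path, "spikes.csv"))
  yaml::write_yaml(list(frame_rate = s$frame_rate,
                        corridor_length = s$corridor_length,
                        n_bins = s$n_bins,
                        n_cells = n_cells(s), n_frames = n_frames(s)),
                   file.path(path, "attributes.yaml"))
  invisible(path)
}

#' Load a session saved by [save_session()]
#'
#' @param path session directory.
#' @return a validated `corridor_session`.
#' @export
load_session <- function(path) {
  if (!dir.exists(path)) stop("session path does not exist: ", path)
  miss <- .session_files[!file.exists(file.path(path, .session_files))]
  if (length(miss)) stop("missing dataset ", paste(miss, collapse = ", "))
  at <- yaml::read_yaml(file.path(path, "attributes.yaml"))
  beh <- data.table::fread(file.path(path, "behavior.csv"),
                           colClasses = list(character = c("time", "position",
                                                           "speed")))
  need <- c("time", "position", "corridor", "lap", "speed", "lick", "reward")
  miss <- setdiff(need, names(beh))
  if (length(miss)) stop("missing dataset ", paste(miss, collapse = ", "))
  fl <- .read_matrix_csv(file.path(path, "fluorescence.csv"), nrow(beh))
  sp <- .read_matrix_csv(file.path(path, "spikes.csv"), nrow(beh))
  new_session(as.numeric(beh$time), as.numeric(beh$position), beh$corridor,
              beh$lap, as.numeric(beh$speed),
              beh$lick > 0, beh$reward > 0, fl, sp,
              frame_rate = at$frame_rate,
              corridor_length = at$corridor_length, n_bins = at$n_bins)
}

#' Segment a session into laps
#'
#' One row per contiguous non-gray corridor traversal; gray timeout frames
#' belong to no lap. Lap correctness follows the go/no-go rule: a rewarded-
#' corridor (R) lap is correct iff it contains at least one lick frame inside
#' the reward zone, an unrewarded (U) lap iff it contains none; only correct
#' R laps are rewarded.
#'
#' @param s a `corridor_session`.
#' @param rz_fraction fraction of the corridor occupied by the reward zone at
#'   the end of the track (default 0.1, i.e. the last ~10 cm of 106).
#' @return data.frame with lap_index, corridor, first_frame, last_frame,
#'   n_frames, rz_licks, correct, rewarded.
#' @export
segment_laps <- function(s, rz_fraction = 0.1) {
  ng <- s$corridor != GRAY
  if (!any(ng))
    return(data.frame(lap_index = integer(0), corridor = character(0),
                      first_frame = integer(0), last_frame = integer(0),
                      n_frames = integer(0), rz_licks = integer(0),
                      correct = logical(0), rewarded = logical(0)))
  idx <- which(ng)
  brk <- c(TRUE, diff(idx) > 1 | diff(s$lap[idx]) != 0)
  run <- cumsum(brk)
  first <- idx[brk]
  last <- idx[c(brk[-1], TRUE)]
  rz_start <- s$corridor_length * (1 - rz_fraction)
  out <- data.frame(
    lap_index = s$lap[first], corridor = s$corridor[first],
    first_frame = first, last_frame = last, n_frames = last - first + 1L)
  rz_lick <- vapply(seq_along(first), function(i) {
    fr <- first[i]:last[i]
    sum(lick_onsets(s$lick[fr]) & s$position[fr] >= rz_start, na.rm = TRUE)
  }, integer(1))
  out$rz_licks <- rz_lick
  out$correct <- ifelse(out$corridor == "R", rz_lick >= 1L, rz_lick == 0L)
  out$rewarded <- out$corridor == "R" & out$correct
  out
}

# a lick event is the rising edge of the per-frame lick boolean
lick_onsets <- function(lick) lick & !c(FALSE, head(lick, -1))

#' Frames retained for spatial analysis
#'
#' True iff the animal is running strictly faster than `v_min` in one of the
#' corridors; gray timeout-zone frames are always excluded.
#'
#' @param s a `corridor_session`.
#' @param v_min speed threshold in cm/s (strict `>`; default 5).
#' @return logical vector, one element per frame.
#' @export
running_mask <- function(s, v_min = 5) {
  stopifnot(v_min >= 0)
  s$speed > v_min & s$corridor != GRAY
}

#' Spatial bin of a track position
#'
#' Bins are 0-based and half-open, `[i*w, (i+1)*w)` with
#' `w = corridor_length/n_bins`; the last bin is closed so that
#' `position == corridor_length` maps to bin `n_bins - 1`.
#'
#' @param position cm, in `[0, corridor_length]` (`NA` passes through).
#' @param corridor_length cm.
#' @param n_bins number of bins.
#' @return integer bin indices in `0:(n_bins-1)`.
#' @export
bin_position <- function(position, corridor_length = 106, n_bins = 50) {
  ok <- is.na(position) | (position >= 0 & position <= corridor_length)
  if (!all(ok)) stop("position out of [0, ", corridor_length, "]")
  b <- floor(position / (corridor_length / n_bins))
  as.integer(pmin(b, n_bins - 1L))
}

#' Restrict a session to a range of laps
#'
#' Keeps exactly the frames of the selected laps plus the gray frames that
#' surround them (the gray run preceding the first selected lap and the gray
#' frames trailing each selected lap). Lap indices are not renumbered.
#'
#' @param s a `corridor_session`.
#' @param laps integer vector of lap indices to keep.
#' @return a `corridor_session` containing only the selected frames.
#' @export
select_epoch <- function(s, laps) {
  if (length(laps) == 0) stop("empty lap range")
  lt <- segment_laps(s)
  if (!all(laps %in% lt$lap_index))
    stop("lap range beyond session: requested ",
         paste(range(laps), collapse = "-"), ", available ",
         paste(range(lt$lap_index), collapse = "-"))
  keep <- s$lap %in% laps
  # gray run immediately preceding the first selected lap
  f0 <- lt$first_frame[match(min(laps), lt$lap_index)]
  if (f0 > 1) {
    i <- f0 - 1L
    while (i >= 1 && s$corridor[i] == GRAY) { keep[i] <- TRUE; i <- i - 1L }
  }
  subset_session(s, which(keep))
}

subset_session <- function(s, idx) {
  new_session(s$time[idx], s$position[idx], s$corridor[idx], s$lap[idx],
              s$speed[idx], s$lick[idx], s$reward[idx],
              s$fluorescence[, idx, drop = FALSE],
              s$spikes[, idx, drop = FALSE],
              frame_rate = s$frame_rate,
              corridor_length = s$corridor_length, n_bins = s$n_bins)
}

#' Spatial zone definitions (0-based bin ranges)
#'
#' Behavioral zones on the 50-bin corridor: reward zone (RZ) bins 45-49 (the
#' last ~10 cm), prezone (PZ) the 5 bins immediately before it (40-44), and
#' control zone (CZ) the 5 bins starting 25 bins before the PZ (15-19).
#' Neural selectivity zones: P1 bins 0-13, P2 14-27, P3 28-41, and a
#' corridor-dependent RZ window, bins 42-45 (U) or 45-48 (R).
#'
#' @param which `"behavior"` or `"neural"`.
#' @return named list of integer bin vectors (0-based).
#' @export
zone_bins <- function(which = c("behavior", "neural")) {
  which <- match.arg(which)
  if (which == "behavior")
    list(rz = 45:49, pz = 40:44, cz = 15:19)
  else
    list(P1 = 0:13, P2 = 14:27, P3 = 28:41, RZ_U = 42:45, RZ_R = 45:48)
}
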