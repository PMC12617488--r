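# session fixtures are generated in code and cached for the duration of a
# test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small default session: 30 cells, 30 laps, mixed tuned/untuned
small_sim <- function() cached("small_sim",
  simulate_session(sim_config(n_cells = 30, n_laps = 30), seed = 101))

# hand-built minimal session: scripted corridor sequence, deterministic
# positions; n_gray gray frames between laps
scripted_session <- function(corridors = c("U", "R", "U"),
                             frames_per_lap = 60, n_gray = 10,
                             n_cells = 2, frame_rate = 30,
                             corridor_length = 106, speed = 30) {
  pos <- cor_id <- lap <- c()
  for (i in seq_along(corridors)) {
    pos <- c(pos, seq(0, corridor_length - 1e-9,
                      length.out = frames_per_lap))
    cor_id <- c(cor_id, rep(corridors[i], frames_per_lap))
    lap <- c(lap, rep(i - 1L, frames_per_lap))
    pos <- c(pos, rep(NA_real_, n_gray))
    cor_id <- c(cor_id, rep("GRAY", n_gray))
    lap <- c(lap, rep(i - 1L, n_gray))
  }
  n <- length(pos)
  new_session(time = seq_len(n) / frame_rate, position = pos,
              corridor = cor_id, lap = lap,
              speed = rep(speed, n), lick = rep(FALSE, n),
              reward = rep(FALSE, n),
              fluorescence = matrix(1, n_cells, n),
              spikes = matrix(0, n_cells, n),
              frame_rate = frame_rate, corridor_length = corridor_length)
}
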