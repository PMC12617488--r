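# one-lap session with controlled spikes for rate-map arithmetic
one_lap_session <- function(spikes_at_bin = NULL, n_bins = 50,
                            frames_per_bin = 30) {
  nfr <- n_bins * frames_per_bin
  pos <- (seq_len(nfr) - 0.5) / nfr * 106
  spk <- matrix(0, 1, nfr)
  if (!is.null(spikes_at_bin)) {
    fr <- which(bin_position(pos) == spikes_at_bin)[1]
    spk[1, fr] <- 1
  }
  new_session(time = seq_len(nfr) / 30, position = pos,
              corridor = rep("U", nfr), lap = rep(0L, nfr),
              speed = rep(10, nfr), lick = rep(FALSE, nfr),
              reward = rep(FALSE, nfr), fluorescence = spk, spikes = spk,
              frame_rate = 30)
}

test_that("rate maps: occupancy normalization and 3-bin smoothing", {
  s <- one_lap_session(spikes_at_bin = 20)   # 1 s occupancy per bin
  raw <- compute_rate_maps(s, smooth = FALSE)$U
  expect_equal(raw$occupancy, rep(1, 50))
  expect_equal(raw$lambda[1, 21], 1)           # 1 spike / 1 s
  expect_equal(sum(raw$lambda[1, ]), 1)
  sm <- compute_rate_maps(s, smooth = TRUE)$U
  expect_equal(sm$lambda[1, 20:22], rep(1 / 3, 3))  # weight spread 1/3
  # doubling occupancy halves the rate
  s2 <- one_lap_session(spikes_at_bin = 20, frames_per_bin = 60)
  raw2 <- compute_rate_maps(s2, smooth = FALSE)$U
  expect_equal(raw2$lambda[1, 21], 0.5)
  # smoothing conserves total spike mass when activity stays in the interior
  set.seed(4)
  s3 <- one_lap_session()
  b0 <- bin_position(s3$position)
  interior <- b0 >= 3 & b0 <= 46
  s3$spikes[1, interior] <- rpois(sum(interior), 0.3)
  c_raw <- compute_rate_maps(s3, smooth = FALSE)$U$lambda[1, ]
  c_sm <- compute_rate_maps(s3, smooth = TRUE)$U$lambda[1, ]
  expect_equal(sum(c_sm), sum(c_raw), tolerance = 1e-9)
})

test_that("even/odd lap parity splits use within-corridor lap order", {
  sim <- small_sim()
  mo <- compute_rate_maps(sim$session, parity = "odd")$U
  me <- compute_rate_maps(sim$session, parity = "even")$U
  ma <- compute_rate_maps(sim$session)$U
  expect_equal(sort(c(mo$lap_ids, me$lap_ids)), ma$lap_ids)
  expect_equal(length(mo$lap_ids) - length(me$lap_ids) <= 1, TRUE)
})

test_that("spatial reliability: identical, noisy and anti-correlated laps", {
  lam <- dnorm(1:50, 25, 4)
  ident <- matrix(rep(lam, 10), 10, 50, byrow = TRUE)
  expect_equal(as.numeric(spatial_reliability(ident, lam)), 1)
  anti <- matrix(rep(max(lam) - lam, 10), 10, 50, byrow = TRUE)
  expect_lt(as.numeric(spatial_reliability(anti, lam)), 0)
  set.seed(5)
  rs <- replicate(200, {
    noise <- matrix(rnorm(10 * 50), 10, 50)
    as.numeric(spatial_reliability(noise, lam))
  })
  expect_lt(abs(mean(rs)), 0.05)
  flat <- matrix(1, 5, 50)
  expect_true(is.na(spatial_reliability(flat, lam)))
})

test_that("tuning specificity closed forms and monotonicity", {
  expect_equal(tuning_specificity(rep(1, 50)), sqrt(12), tolerance = 1e-9)
  single <- c(rep(0, 20), 1, rep(0, 29))
  expect_equal(tuning_specificity(single), 50 * sqrt(12), tolerance = 1e-9)
  # narrower Gaussian -> larger specificity
  specs <- vapply(c(16, 12, 8, 4), function(sg)
    tuning_specificity(dnorm((1:50 - 0.5) * 2.12, 53, sg)), numeric(1))
  expect_true(all(diff(specs) > 0))
  expect_true(is.na(tuning_specificity(rep(0, 50))))
})

test_that("Skaggs information closed forms and invariances", {
  occ <- rep(1, 50)
  expect_equal(spatial_information(rep(2, 50), occ), 0)
  single <- c(rep(0, 49), 3)
  expect_equal(spatial_information(single, occ), log2(50), tolerance = 1e-9)
  lam <- dnorm(1:50, 30, 5)
  expect_equal(spatial_information(lam, occ),
               spatial_information(7 * lam, occ), tolerance = 1e-12)
  expect_equal(spatial_information(lam, occ, per = "second"),
               spatial_information(lam, occ) * mean(lam), tolerance = 1e-9)
  expect_true(is.na(spatial_information(rep(0, 50), occ)))
})

test_that("corridor selectivity: boundaries, formula and recovery", {
  sim <- cached("sel_sim",
    simulate_session(sim_config(n_cells = 50, n_laps = 60, frac_tuned = 1, baseline_hz = 0,
                                gain = 3, rz_overrep = 0,
                                pz_slow_factor = 1),
                     seed = 41))
  sel <- corridor_selectivity(sim$session)
  expect_true(all(abs(sel$whole) <= 1, na.rm = TRUE))
  expect_lt(abs(mean(sel$whole, na.rm = TRUE) - 0.5), 0.05)
  # boundary: spikes only in R -> +1
  s <- scripted_session(c("U", "R"))
  lt <- segment_laps(s)
  s$spikes[1, lt$first_frame[2]:lt$last_frame[2]] <- 1
  sel2 <- corridor_selectivity(s)
  expect_equal(sel2$whole[1], 1)
  # antisymmetry under corridor swap
  s_swap <- s
  s_swap$corridor[s_swap$corridor == "U"] <- "x"
  s_swap$corridor[s_swap$corridor == "R"] <- "U"
  s_swap$corridor[s_swap$corridor == "x"] <- "R"
  sel3 <- corridor_selectivity(s_swap)
  expect_equal(sel3$whole[1], -sel2$whole[1])
  # invariance under uniform time rescaling (double every frame)
  idx <- rep(seq_along(s$time), each = 2)
  s2 <- new_session(seq_along(idx) / 30, s$position[idx], s$corridor[idx],
                    s$lap[idx], s$speed[idx], s$lick[idx], s$reward[idx],
                    s$fluorescence[, idx, drop = FALSE],
                    s$spikes[, idx, drop = FALSE], frame_rate = 30)
  expect_equal(corridor_selectivity(s2)$whole[1], sel2$whole[1])
})

test_that("direct formula cases for rate ratios", {
  # rrew = 3, runrew = 1 -> 0.5 ; equal rates -> 0
  expect_equal((3 - 1) / (3 + 1), 0.5)
  s <- scripted_session(c("U", "R"))
  lt <- segment_laps(s)
  fu <- lt$first_frame[1]:lt$last_frame[1]
  fr <- lt$first_frame[2]:lt$last_frame[2]
  s$spikes[1, fr[1:30]] <- 3; s$spikes[1, fu[1:30]] <- 1
  expect_equal(corridor_selectivity(s)$whole[1], 0.5)
})

test_that("shuffle null is calibrated and detects planted fields", {
  # homogeneous Poisson cells: information p-values are uniform
  simn <- cached("null_sim_small",
    simulate_session(sim_config(n_cells = 80, n_laps = 60, frac_tuned = 0),
                     seed = 51))
  set.seed(52)
  tsn <- cached("null_tun_small",
    tuning_significance(simn$session, shuffle_config(n_shuffles = 200)))
  pU <- tsn$metrics$p_information[tsn$metrics$corridor == "U"]
  ks <- suppressWarnings(stats::ks.test(pU, "punif"))
  expect_gt(ks$p.value, 0.01)
  # a planted strong field is highly significant on every spatial metric;
  # the p-values need not reach the permutation floor because laps of the
  # simulated task have similar durations, so a circular shift relocates
  # the field semi-coherently until the chunk permutation and the
  # pseudorandom corridor schedule break the alignment
  simp <- simulate_session(sim_config(n_cells = 1, n_laps = 60,
                                      frac_tuned = 1, baseline_hz = 1,
                                      field_amp_hz = 10), seed = 53)
  set.seed(54)
  tsp <- tuning_significance(simp$session, shuffle_config(n_shuffles = 1000))
  expect_lte(min(tsp$metrics$p_reliability), 0.01)
  expect_lte(min(tsp$metrics$p_information), 0.01)
  expect_error(shuffle_config(n_shuffles = 0), "n_shuffles")
  expect_error(
    tuning_significance(simp$session,
                        shuffle_config(min_chunk_frames = 1e6)),
    "lower n_chunks")
})

test_that("Holm-Bonferroni classification arithmetic", {
  mk_tun <- function(p_spatial, p_sel) {
    metrics <- data.frame(
      cell = 1, corridor = c("U", "R"),
      reliability = 0.5, specificity = 4, information = 1,
      p_reliability = p_spatial[1:2], p_specificity = p_spatial[3:4],
      p_information = p_spatial[5:6])
    selectivity <- data.frame(cell = 1, whole = 0, P1 = 0, P2 = 0, P3 = 0,
                              RZ = 0, p_whole = p_sel[1], p_P1 = p_sel[2],
                              p_P2 = p_sel[3], p_P3 = p_sel[4],
                              p_RZ = p_sel[5])
    list(metrics = metrics, selectivity = selectivity)
  }
  # all raw p = 1 -> active-untuned
  c0 <- classify_cells(mk_tun(rep(1, 6), rep(1, 5)))
  expect_equal(c0$category, "active-untuned")
  # smallest raw p = 0.004 < 0.05/11 in a spatial metric -> spatial-only
  c1 <- classify_cells(mk_tun(c(0.004, rep(0.9, 5)), rep(0.9, 5)))
  expect_equal(c1$category, "spatial-only")
  expect_true(c1$tuned_U); expect_false(c1$tuned_R)
  # p = 0.005 > 0.05/11 fails the first Holm step -> untuned
  c2 <- classify_cells(mk_tun(c(0.005, rep(0.9, 5)), rep(0.9, 5)))
  expect_equal(c2$category, "active-untuned")
  # both families significant -> dual; inactive flag wins
  c3 <- classify_cells(mk_tun(c(0.001, rep(0.9, 5)), c(0.002, rep(0.9, 4))))
  expect_equal(c3$category, "dual")
  c4 <- classify_cells(mk_tun(c(0.001, rep(0.9, 5)), rep(0.9, 5)),
                       active = FALSE)
  expect_equal(c4$category, "inactive")
})

test_that("peak sorting and tuned-fraction profiles", {
  m <- rbind(c(0, 0, 0, 5, 0), c(9, 0, 0, 0, 0), c(0, 4, 0, 0, 0))
  sp <- sort_by_peak(m)
  expect_equal(sp$order, c(2, 3, 1))
  expect_equal(sp$peak_bin, c(3L, 0L, 1L))
  # tie at the same peak bin: stable order by cell id
  m2 <- rbind(c(1, 5, 0), c(2, 6, 0), c(7, 0, 0))
  expect_equal(sort_by_peak(m2)$order, c(3, 1, 2))
  norm <- sort_by_peak(m, normalize = TRUE)$sorted
  expect_equal(unname(apply(norm, 1, max)), rep(1, 3))
  # tuned-fraction profile concentrates where fields are planted
  prof <- tuned_fraction_by_position(c(TRUE, TRUE, FALSE), m)
  expect_equal(sum(prof), 2 / 3)
  expect_equal(prof[c(1, 4)], c(1 / 3, 1 / 3))
  expect_equal(tuned_fraction_by_position(c(FALSE, FALSE, FALSE), m),
               rep(0, 5))
})

test_that("cross-sorted noiseless maps are near-diagonal", {
  sim <- cached("diag_sim",
    simulate_session(sim_config(n_cells = 60, n_laps = 40, frac_tuned = 1,
                                baseline_hz = 0, field_amp_hz = 40,
                                rz_overrep = 0), seed = 61))
  modd <- compute_rate_maps(sim$session, parity = "odd")$U$lambda
  meven <- compute_rate_maps(sim$session, parity = "even")$U$lambda
  sp <- sort_by_peak(modd)
  pk_even <- apply(meven[sp$order, ], 1, which.max)
  # even-lap peaks follow the odd-lap ordering (quantified diagonality)
  expect_lte(mean(abs(pk_even - sort(pk_even))), 1)
})
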