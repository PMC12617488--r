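test_that("posterior equals brute-force enumeration on small instances", {
  for (k in 1:20) {
    nn <- sample(1:5, 1); nb <- sample(2:5, 1)
    model <- random_model(nn, nb, seed = 100 + k)
    svec <- rbinom(nn, 1, 0.5)
    po <- posterior(model, svec)
    expect_lt(max(abs(po$joint$posterior - brute_posterior(model, svec))),
              1e-12)
    expect_equal(sum(po$joint$posterior), 1, tolerance = 1e-12)
    # marginals recomputed from the joint match the stored marginals
    jx <- tapply(po$joint$posterior, po$joint$bin, sum)
    expect_equal(as.numeric(jx), as.numeric(po$p_x), tolerance = 1e-12)
    jc <- tapply(po$joint$posterior, po$joint$corridor, sum)
    expect_equal(as.numeric(jc), as.numeric(po$p_c), tolerance = 1e-12)
  }
})

test_that("posterior symmetry, degenerate neurons and median rule", {
  # identical P across corridors -> P(c|s) exactly (0.5, 0.5)
  m <- random_model(4, 6, seed = 200)
  m$P <- cbind(m$P[, 1:6], m$P[, 1:6])
  po <- posterior(m, c(1, 0, 1, 1))
  expect_equal(as.numeric(po$p_c), c(0.5, 0.5), tolerance = 1e-12)
  # a neuron with constant P contributes no discrimination
  m2 <- random_model(3, 5, seed = 201)
  m3 <- m2; m3$P <- rbind(m3$P, rep(0.4, 10))
  p2 <- posterior(m2, c(1, 0, 0))
  p3 <- posterior(m3, c(1, 0, 0, 1))
  expect_equal(p2$joint$posterior, p3$joint$posterior, tolerance = 1e-12)
  # concentrated likelihood pulls the posterior to its state
  m4 <- random_model(1, 5, seed = 202)
  m4$P[1, ] <- 1e-9; m4$P[1, 7] <- 1 - 1e-9
  p4 <- posterior(m4, 1)
  expect_gt(p4$joint$posterior[7], 0.999)
  expect_equal(p4$pred_bin, m4$states$bin[7])
  expect_equal(p4$pred_corridor, m4$states$corridor[7])
  # median = smallest bin with cumulative marginal >= 0.5
  m5 <- random_model(1, 2, n_corr = 1, seed = 203)
  m5$P[1, ] <- 0.5
  p5 <- posterior(m5, 1)   # uniform posterior over 2 bins
  expect_equal(p5$pred_bin, 0L)
})

test_that("decoder fit arithmetic and pseudocount guard", {
  B <- matrix(1, 1, 10)  # one neuron firing in every frame
  m <- fit_decoder(B, bin = rep(0, 10), corridor = rep("A", 10),
                   decoder_config(pseudocount = 0.5))
  expect_equal(m$P[1, 1], 10.5 / 11)
  expect_error(decoder_config(pseudocount = 0), "pseudocount")
  # states with no training frames are flagged unusable
  B2 <- matrix(rbinom(20, 1, 0.5), 2, 10)
  m2 <- fit_decoder(B2, bin = rep(c(0, 1), 5),
                    corridor = rep(c("A", "B"), each = 5),
                    decoder_config())
  expect_equal(sum(m2$usable), length(unique(paste(rep(c(0, 1), 5),
                                                   rep(c("A", "B"),
                                                       each = 5)))))
})

test_that("preprocessing filters frames as specified", {
  s <- scripted_session(c("U", "R"), frames_per_lap = 60)
  s$spikes[1, ] <- 0.6
  pp <- preprocess_for_decoding(s, decoder_config())
  # constant 0.6 after moving sum > 0.5 -> all ones
  expect_true(all(pp$B[1, ] == 1))
  # first 2% of the track (bin 0) omitted
  expect_true(all(pp$bin >= 1))
  expect_true(all(pp$corridor != "GRAY"))
  # laps shorter than 40 frames are dropped entirely
  s39 <- scripted_session(c("U", "R"), frames_per_lap = 39)
  expect_error(preprocess_for_decoding(s39, decoder_config()),
               "no frames retained")
  # mixed: only the long lap survives
  smix <- scripted_session(c("U", "R"), frames_per_lap = 80)
  lt <- segment_laps(smix)
  drop <- lt$first_frame[2]:lt$last_frame[2]
  smix$corridor[drop[40:80]] <- "GRAY"
  smix$position[drop[40:80]] <- NA
  ppm <- preprocess_for_decoding(smix, decoder_config())
  expect_true(all(ppm$lap == 0))
  # slow frames removed (strictly below the floor)
  sslow <- scripted_session(c("U"), frames_per_lap = 80)
  sslow$speed[1:10] <- 2
  pps <- preprocess_for_decoding(sslow, decoder_config())
  expect_false(any(pps$frame %in% 1:10))
  # all-gray session
  sg <- scripted_session(c("U"))
  sg$corridor[] <- "GRAY"; sg$position[] <- NA
  expect_error(preprocess_for_decoding(sg, decoder_config()),
               "no frames retained")
})

test_that("cross-validated decoding: chance level and high-SNR recovery", {
  # corridors share tuning (g = 1): corridor decoding at chance
  simc <- cached("dec_chance_sim",
    simulate_session(sim_config(n_cells = 60, n_laps = 40, frac_tuned = 1),
                     seed = 81))
  resc <- decode_cross_validated(simc$session, decoder_config(), seed = 82)
  expect_lt(abs(mean(resc$corridor_error) - 0.5), 0.05)
  # disjoint fields per corridor: low corridor error, small position error
  simd <- cached("dec_disjoint_sim",
    simulate_session(sim_config(n_cells = 100, n_laps = 40, frac_tuned = 1,
                                field_corridor = rep(c("U", "R"), 50)),
                     seed = 83))
  resd <- decode_cross_validated(simd$session, decoder_config(), seed = 84)
  ebp <- error_by_position(resd)
  late <- ebp[ebp$true_bin >= 5, ]
  expect_lte(weighted.mean(late$corridor_error, late$n_frames), 0.05)
  expect_lte(median(resd$pos_error), 2)
  # fewer neurons than the subsample size: repeats are degenerate
  expect_equal(attr(resd, "n_subsamples"), 1L)
  expect_equal(attr(resd, "n_neurons_used"), 100L)
})

test_that("decoding quality is monotone in field SNR", {
  errs <- vapply(c(0.5, 2, 6, 20), function(amp) {
    sim <- simulate_session(
      sim_config(n_cells = 50, n_laps = 30, frac_tuned = 1,
                 field_amp_hz = amp,
                 field_corridor = rep(c("U", "R"), 25)), seed = 85)
    res <- decode_cross_validated(sim$session, decoder_config(), seed = 86)
    mean(res$corridor_error)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0.02))  # non-increasing up to noise
})

test_that("error curves report missing bins as absent, not zero", {
  res <- data.frame(true_bin = c(1, 1, 2), true_corridor = "U",
                    pred_bin = c(1, 1, 2), pred_corridor = "U",
                    corridor_error = 0, soft_corridor_error = 0.1,
                    pos_error = 0)
  ebp <- error_by_position(res)
  expect_equal(ebp$true_bin, c(1, 2))
  expect_equal(ebp$corridor_error, c(0, 0))
  expect_error(error_by_position(res[0, ]), "empty")
})
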