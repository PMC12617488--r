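test_that("PV correlation: identity, permutation and reordering", {
  set.seed(6)
  A <- matrix(rnorm(200 * 50, 5), 200, 50)
  pv <- pv_correlation(A, A)
  expect_equal(pv$diagonal, rep(1, 50))
  # permuting the cells of one condition destroys the correspondence
  B <- A[sample(200), ]
  expect_lt(abs(mean(pv_correlation(A, B)$diagonal)), 0.05)
  # independent random maps: near-zero diagonal
  C <- matrix(rnorm(200 * 50, 5), 200, 50)
  expect_lt(abs(mean(pv_correlation(A, C)$diagonal)), 0.05)
  # invariance under a common reordering of cells
  ord <- sample(200)
  pv2 <- pv_correlation(A[ord, ], C[ord, ])
  expect_equal(pv2$M, pv_correlation(A, C)$M, tolerance = 1e-12)
  expect_error(pv_correlation(A[1, , drop = FALSE], C[1, , drop = FALSE]),
               "2 cells")
})

test_that("lap-to-lap correlation matrix structure around a switch", {
  sim <- cached("switch_sim_small", simulate_session(
    inject_switch(sim_config(n_cells = 60, n_laps = 50, frac_tuned = 1),
                  event_lap = 24, remap_frac = 1), seed = 71))
  ll <- lap_to_lap_correlation(sim$session, event_lap = 24, window = 10)
  for (cc in names(ll)) {
    C <- ll[[cc]]$C
    expect_equal(C, t(C))
    expect_equal(diag(C), rep(1, nrow(C)))
    post <- ll[[cc]]$is_post
    within_pre <- mean(C[!post, !post][upper.tri(C[!post, !post])],
                       na.rm = TRUE)
    cross <- mean(C[!post, post], na.rm = TRUE)
    expect_gt(within_pre, cross)
    # C_i equals the row mean excluding the diagonal
    off <- C; diag(off) <- NA
    expect_equal(ll[[cc]]$C_i, rowMeans(off, na.rm = TRUE))
  }
  expect_error(lap_to_lap_correlation(sim$session, event_lap = 24,
                                      window = 30), "insufficient laps")
})

test_that("no block structure without remapping", {
  sim <- cached("noswitch_sim", simulate_session(
    sim_config(n_cells = 60, n_laps = 50, frac_tuned = 1), seed = 72))
  ll <- lap_to_lap_correlation(sim$session, event_lap = 24, window = 10)
  C <- ll$U$C; post <- ll$U$is_post
  within <- mean(C[!post, !post][upper.tri(C[!post, !post])], na.rm = TRUE)
  cross <- mean(C[!post, post], na.rm = TRUE)
  expect_lt(abs(within - cross), 0.05)
})

test_that("template correlation: identity lap and drift decrease", {
  sim <- cached("drift_sim", simulate_session(
    inject_reversal_drift(sim_config(n_cells = 80, n_laps = 80,
                                     frac_tuned = 1),
                          event_lap = 30, drift_sd_cm = 2), seed = 73))
  tc <- template_correlation(sim$session, event_lap = 30, corridor = "U",
                             template = "pre", exclude = 8)
  expect_true(all(tc$B[!is.na(tc$B)] <= 1 & tc$B[!is.na(tc$B)] >= -1))
  pre <- tc[!tc$is_post, ]
  post <- tc[tc$is_post, ]
  expect_gt(mean(pre$B, na.rm = TRUE), mean(post$B, na.rm = TRUE))
  expect_lt(cor(post$lap, post$B, method = "spearman"), -0.5)
  # correlation to the post template increases across post laps under drift
  tcp <- template_correlation(sim$session, event_lap = 30, corridor = "U",
                              template = "post", exclude = 8)
  pp <- tcp[tcp$is_post, ]
  early <- mean(head(pp$B, 5), na.rm = TRUE)
  late <- mean(tail(pp$B, 5), na.rm = TRUE)
  expect_lt(early, late)
  expect_error(template_correlation(sim$session, event_lap = 30,
                                    corridor = "U", template = "pre",
                                    exclude = 1000), "empty template")
})

test_that("normalized activity difference", {
  A <- rbind(c(3, 1, 3, 1), c(2, 2, 2, 2))
  B <- rbind(c(1, 3, 1, 3), c(2, 2, 2, 2))
  nd <- normalized_activity_difference(A, B)
  # differenced row (2,-2,2,-2) scaled to unit SD
  expect_equal(sd(nd$diff[1, ]), 1)
  expect_equal(nd$diff[1, ], c(2, -2, 2, -2) / sd(c(2, -2, 2, -2)))
  # A == B row: zero SD, flagged undefined
  expect_true(nd$flagged[2])
  expect_true(all(is.na(nd$diff[2, ])))
  # common positive rescaling leaves the result unchanged
  nd2 <- normalized_activity_difference(5 * A, 5 * B)
  expect_equal(nd2$diff[1, ], nd$diff[1, ])
})

test_that("transition table expectation and chi-square", {
  # equal source groups, all entering one target: expected = n/groups each
  src <- rep(c("a", "b", "c"), each = 30)
  tgt <- rep("dual", 90)
  tt <- transition_table(src, tgt)
  expect_equal(unname(tt$expected[, 1]), rep(30, 3))
  expect_equal(tt$chisq, 0)
  # observed == expected -> chi-square 0, p = 1
  src2 <- rep(c("a", "b"), each = 20)
  tgt2 <- rep(c("x", "y"), 20)
  tt2 <- transition_table(src2, tgt2)
  expect_equal(tt2$chisq, 0)
  expect_equal(tt2$p, 1)
  # hand-built table equals the textbook statistic and stats::chisq.test
  src3 <- c(rep("a", 25), rep("b", 35), rep("c", 30))
  tgt3 <- c(rep("x", 10), rep("y", 15), rep("x", 30), rep("y", 5),
            rep("x", 12), rep("y", 18))
  tt3 <- transition_table(src3, tgt3)
  ref <- suppressWarnings(stats::chisq.test(table(src3, tgt3),
                                            correct = FALSE))
  expect_equal(tt3$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt3$p, ref$p.value, tolerance = 1e-12)
  # totals conserved per target category
  expect_equal(colSums(tt3$expected), colSums(unclass(tt3$observed)) + 0)
  expect_error(transition_table(character(0), character(0)), "empty")
})

test_that("ROI matching by trace correlation", {
  set.seed(8)
  n <- 5; T1 <- 3000; T2 <- 3000
  tr1 <- matrix(rnorm(n * T1), n, T1)
  tr2 <- matrix(rnorm(n * T2), n, T2)
  concat <- cbind(tr1, tr2)              # reference = same cells
  m <- match_rois(tr1, tr2, concat)
  expect_equal(sum(m$matched), n)
  expect_equal(m$roi1[m$matched], m$roi2[m$matched])
  # independent noise: no matches at 10-min trace lengths
  tr2b <- matrix(rnorm(n * T2), n, T2)
  concat2 <- cbind(matrix(rnorm(n * T1), n, T1), tr2b)
  m2 <- match_rois(tr1, tr2b, concat2)
  expect_equal(sum(m2$matched), 0)
  # one ROI matching two partners: all its pairs are removed
  tr1c <- tr1
  tr2c <- rbind(tr2[1, ] + rnorm(T2, 0, 0.01), tr2)  # rois 1,2 both ~ ref 1
  concat3 <- cbind(tr1c, tr2)
  m3 <- match_rois(tr1c, tr2c, concat3)
  expect_false(any(m3$matched[m3$roi1 == 1]))
  expect_error(match_rois(tr1, tr2, concat[, -1]), "expected")
})
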