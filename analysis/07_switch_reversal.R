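#!/usr/bin/env Rscript
# Reorganization analyses around the scripted events: lap-to-lap population
# correlation and PV correlations across the Switch (abrupt remapping), and
# lapwise correlation to the pre-event template across the Reversal
# (gradual drift), split by lap correctness.

library(corridorcode)

out_dir <- "results/analysis"

## Switch session: block structure of the lap-to-lap correlation
sw <- load_session("scratch/sessions/switch")
ll <- lap_to_lap_correlation(sw, event_lap = 44, window = 20)
ci <- do.call(rbind, lapply(names(ll), function(cc)
  data.frame(corridor = cc, lap = ll[[cc]]$lap_ids,
             is_post = ll[[cc]]$is_post, C_i = ll[[cc]]$C_i)))
write.csv(ci, file.path(out_dir, "switch_lap_correlation.csv"),
          row.names = FALSE)
for (cc in names(ll)) {
  C <- ll[[cc]]$C; post <- ll[[cc]]$is_post
  cat(sprintf(
    "switch %s: within-pre %.3f | within-post %.3f | cross %.3f\n", cc,
    mean(C[!post, !post][upper.tri(C[!post, !post])], na.rm = TRUE),
    mean(C[post, post][upper.tri(C[post, post])], na.rm = TRUE),
    mean(C[!post, post], na.rm = TRUE)))
}

pre <- compute_rate_maps(sw, laps = 0:43)
post <- compute_rate_maps(sw, laps = 44:89)
preo <- compute_rate_maps(sw, laps = 0:43, parity = "odd")
pree <- compute_rate_maps(sw, laps = 0:43, parity = "even")
for (cc in c("U", "R")) {
  d_pp <- pv_correlation(pre[[cc]]$lambda, post[[cc]]$lambda)$diagonal
  d_oe <- pv_correlation(preo[[cc]]$lambda, pree[[cc]]$lambda)$diagonal
  write.csv(data.frame(bin = 0:49, pre_post = d_pp, odd_even = d_oe),
            file.path(out_dir, sprintf("switch_pv_diagonal_%s.csv", cc)),
            row.names = FALSE)
  cat(sprintf("switch %s: PV diag pre/post %.3f vs odd/even %.3f\n", cc,
              mean(d_pp, na.rm = TRUE), mean(d_oe, na.rm = TRUE)))
}

## Reversal session: gradual departure from the pre-event template
rv <- load_session("scratch/sessions/reversal")
for (cc in c("U", "R")) {
  tc <- template_correlation(rv, event_lap = 60, corridor = cc,
                             template = "pre", exclude = 20)
  write.csv(tc, file.path(out_dir,
                          sprintf("reversal_template_corr_%s.csv", cc)),
            row.names = FALSE)
  post_tc <- tc[tc$is_post, ]
  rho <- cor(post_tc$lap, post_tc$B, method = "spearman")
  cat(sprintf("reversal %s: Spearman(lap, B) = %.3f over %d post laps\n",
              cc, rho, nrow(post_tc)))
  by_corr <- tapply(post_tc$B, post_tc$correct, mean, na.rm = TRUE)
  cat(sprintf("reversal %s: mean B correct %.3f | error %.3f\n", cc,
              by_corr["TRUE"], by_corr["FALSE"]))
}
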