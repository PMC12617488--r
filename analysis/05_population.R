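#!/usr/bin/env Rscript
# Population-level comparisons on the learning session: PV correlations of
# the U and R corridor maps within the LOW and HIGH epochs (odd vs even
# laps as the within-condition reference), the LOW -> HIGH category
# transition table against a random-transition expectation, and the
# normalized activity difference between epochs.

library(corridorcode)

out_dir <- "results/analysis"
s <- load_session("scratch/sessions/learning")
lt <- segment_laps(s)
perf <- performance_series(lt$correct)
epochs <- list(LOW = find_epoch(perf, "LOW"), HIGH = find_epoch(perf, "HIGH"))

for (ep in names(epochs)) {
  laps <- epochs[[ep]]
  maps <- compute_rate_maps(s, laps = laps)
  pv_ur <- pv_correlation(maps$U$lambda, maps$R$lambda)
  oddU <- compute_rate_maps(s, laps = laps, parity = "odd")$U$lambda
  evenU <- compute_rate_maps(s, laps = laps, parity = "even")$U$lambda
  pv_oe <- pv_correlation(oddU, evenU)
  write.csv(data.frame(bin = 0:49, UR = pv_ur$diagonal,
                       odd_even_U = pv_oe$diagonal),
            file.path(out_dir, paste0("pv_diagonals_", ep, ".csv")),
            row.names = FALSE)
  cat(sprintf("%s: mean PV diag U-vs-R %.3f | odd-vs-even (U) %.3f\n", ep,
              mean(pv_ur$diagonal, na.rm = TRUE),
              mean(pv_oe$diagonal, na.rm = TRUE)))
  nd <- normalized_activity_difference(maps$U$lambda, maps$R$lambda)
  cat(sprintf("%s: %d cells with undefined normalized U-R difference\n",
              ep, sum(nd$flagged)))
}

cats <- read.csv(file.path(out_dir, "cell_categories.csv"))
tt <- transition_table(cats$category[cats$epoch == "LOW"],
                       cats$category[cats$epoch == "HIGH"])
obs <- as.data.frame(tt$observed)
obs$expected <- as.numeric(t(tt$expected))[
  match(paste(obs$source, obs$target),
        paste(rep(rownames(tt$expected), each = ncol(tt$expected)),
              rep(colnames(tt$expected), nrow(tt$expected))))]
write.csv(obs, file.path(out_dir, "transition_table.csv"), row.names = FALSE)
cat(sprintf("category transitions: chi-square %.2f (df %d), p = %.3g\n",
            tt$chisq, tt$df, tt$p))
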