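#!/usr/bin/env Rscript
# Behavioral scoring of the learning session: lap correctness, moving-window
# performance with LOW/MED/HIGH epoch labels, spatially binned lick rate and
# speed, and the intracorridor indices / intercorridor selectivities.

library(corridorcode)

out_dir <- "results/analysis"
s <- load_session("scratch/sessions/learning")

lt <- segment_laps(s)
write.csv(lt, file.path(out_dir, "lap_table.csv"), row.names = FALSE)

perf <- performance_series(lt$correct)
write.csv(perf, file.path(out_dir, "performance_series.csv"),
          row.names = FALSE)
cat("criterion lap (36/40 correct):", attr(perf, "criterion_lap"), "\n")

low <- find_epoch(perf, "LOW")
high <- find_epoch(perf, "HIGH")
cat("LOW epoch:", length(low), "laps; HIGH epoch:", length(high), "laps\n")

rows <- list()
for (ep in c("LOW", "HIGH")) {
  laps <- if (ep == "LOW") low else high
  if (is.null(laps)) next
  bb <- bin_behavior(s, laps = laps)
  bb$bins$epoch <- ep
  rows[[ep]] <- bb$bins
  for (q in c("lick_rate", "speed"))
    cat(sprintf(
      "%s %-9s: index U % .3f | index R % .3f | selectivity % .3f\n",
      ep, q, lick_speed_index(bb, "U", q), lick_speed_index(bb, "R", q),
      intercorridor_selectivity(bb, q)))
}
write.csv(do.call(rbind, rows), file.path(out_dir, "behavior_binned.csv"),
          row.names = FALSE)
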