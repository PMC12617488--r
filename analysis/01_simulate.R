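#!/usr/bin/env Rscript
# Generate the synthetic study sessions used by the downstream analysis
# scripts: a learning session (LOW-stage laps followed by HIGH-stage laps),
# a context-Switch session (abrupt remapping of half the population) and a
# reward-Reversal session (gradual drift of field centers). Sessions are
# written under scratch/sessions/ (regenerated on demand, not shipped);
# per-lap tables and ground-truth summaries go to results/analysis/.

library(corridorcode)

out_dir <- "results/analysis"
ses_dir <- "scratch/sessions"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(ses_dir, recursive = TRUE, showWarnings = FALSE)

seed <- 20260926

cfg_learning <- sim_config(n_cells = 100, n_laps = 120, stage = "LOW",
                           stage_change_lap = 60)
cfg_switch <- inject_switch(sim_config(n_cells = 100, n_laps = 90,
                                       frac_tuned = 1),
                            event_lap = 44, remap_frac = 1)
cfg_reversal <- inject_reversal_drift(sim_config(n_cells = 100,
                                                 n_laps = 140,
                                                 frac_tuned = 1),
                                      event_lap = 60, drift_sd_cm = 2)

sims <- list(learning = simulate_session(cfg_learning, seed),
             switch = simulate_session(cfg_switch, seed + 1),
             reversal = simulate_session(cfg_reversal, seed + 2))

for (nm in names(sims)) {
  save_session(sims[[nm]]$session, file.path(ses_dir, nm))
  tr <- sims[[nm]]$truth
  write.csv(tr$cells, file.path(out_dir, paste0("truth_cells_", nm, ".csv")),
            row.names = FALSE)
  write.csv(tr$laps, file.path(out_dir, paste0("truth_laps_", nm, ".csv")),
            row.names = FALSE)
  lt <- segment_laps(sims[[nm]]$session)
  cat(sprintf("%-9s: %d laps (%d U / %d R), %d cells, %.1f min\n", nm,
              nrow(lt), sum(lt$corridor == "U"), sum(lt$corridor == "R"),
              nrow(sims[[nm]]$session$spikes),
              length(sims[[nm]]$session$time) / 30 / 60))
}
cat("sessions in", ses_dir, "; ground truth in", out_dir, "\n")
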