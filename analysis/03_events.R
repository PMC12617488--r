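#!/usr/bin/env Rscript
# Calcium-event detection on the learning session: dF/F with a mode
# baseline, cell-specific noise SD from resting segments, transients above
# 3 noise SD separated by >= 5 s, and the active / sufficiently-active
# classification used downstream.

library(corridorcode)

out_dir <- "results/analysis"
s <- load_session("scratch/sessions/learning")

at <- activity_table(s)
write.csv(at, file.path(out_dir, "activity_table.csv"), row.names = FALSE)

cat(sprintf("cells: %d | active (>= 1 event/min): %d | > 1 Hz: %d\n",
            nrow(at), sum(at$is_active), sum(at$is_sufficiently_active)))
cat(sprintf("median noise SD: %.3f dF/F | median rate: %.2f events/s\n",
            median(at$noise_sd, na.rm = TRUE),
            median(at$mean_rate_hz)))
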