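#!/usr/bin/env Rscript
# Naive-Bayes decoding of joint (position, corridor) from binarized spikes
# on the HIGH epoch of the learning session, 10-fold cross-validated, with
# per-position corridor-identity and position error curves.

library(corridorcode)

out_dir <- "results/analysis"
s <- load_session("scratch/sessions/learning")
lt <- segment_laps(s)
perf <- performance_series(lt$correct)
high <- find_epoch(perf, "HIGH")
e <- select_epoch(s, high)

res <- decode_cross_validated(e, decoder_config(), seed = 2)
ebp <- error_by_position(res)
write.csv(ebp, file.path(out_dir, "decoding_error_by_position.csv"),
          row.names = FALSE)

cat(sprintf("HIGH epoch: %d test frames, %d neurons (%d subsample repeats)\n",
            nrow(res), attr(res, "n_neurons_used"),
            attr(res, "n_subsamples")))
cat(sprintf("corridor error %.3f (soft %.3f) | median |pos error| %d bins\n",
            mean(res$corridor_error), mean(res$soft_corridor_error),
            as.integer(median(res$pos_error))))
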