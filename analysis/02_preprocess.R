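#!/usr/bin/env Rscript
# Stage 2: artifact rejection, interpolation, average reference.
#
# Synthetic epochs are already band-limited, so the FIR filter and the
# resampler are exercised by the test suite rather than rerun here; this
# stage applies the amplitude / high-frequency rejection rules and the
# average reference, and reports per-sample trial retention.

library(ersplearn)

out <- "results"
sc <- readRDS(file.path(out, "data", "scenario.rds"))
names_all <- c(t(outer(seq_len(sc$cfg$n_subjects), c("Go", "NoGo"),
                       function(s, cnd) paste0(s, ".", cnd))))

esets <- list()
retention <- data.frame()
for (nm in names_all) {
  raw <- read_epochs(file.path(out, "data", nm))
  pre <- preprocess_epochs(raw)
  esets[[nm]] <- pre
  retention <- rbind(retention, data.frame(
    sample = nm, trials_in = dim(raw$data)[1], trials_kept = dim(pre$data)[1]))
}
saveRDS(esets, file.path(out, "data", "preprocessed.rds"))
write.table(retention, file.path(out, "retention.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("retained %.1f%% of trials overall (range %.0f%%-%.0f%% per sample)\n",
            100 * sum(retention$trials_kept) / sum(retention$trials_in),
            100 * min(retention$trials_kept / retention$trials_in),
            100 * max(retention$trials_kept / retention$trials_in)))
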