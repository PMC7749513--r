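#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-subject Go/NoGo cohort.
#
# The desk-scale study conditions: 12 subjects, 24 channels, 40 Go / 10 NoGo
# trials at 128 Hz, five dipolar sources, and ten planted condition-specific
# band x epoch effects (the ground truth the rest of the workflow must
# recover). Epochs are written as portable containers, the truth as TSV.

library(ersplearn)

seed <- 1L
out <- "results"
dir.create(file.path(out, "data"), recursive = TRUE, showWarnings = FALSE)

sc <- scaled_scenario(seed = seed)
esets <- simulate_cohort(sc$cfg, sc$truth)

for (nm in names(esets)) {
  write_epochs(esets[[nm]], file.path(out, "data", nm))
}
saveRDS(sc, file.path(out, "data", "scenario.rds"))

truth <- scaled_effect_table()
write.table(truth, file.path(out, "planted_effects.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("simulated %d subjects x 2 conditions (%d + %d trials) at %g Hz\n",
            sc$cfg$n_subjects, sc$cfg$trials_go, sc$cfg$trials_nogo,
            sc$cfg$sample_rate_hz))
cat(sprintf("planted %d effects over %d sources; containers under %s/data\n",
            nrow(truth), length(sc$truth$sources), out))
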