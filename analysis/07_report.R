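#!/usr/bin/env Rscript
# Stage 7: assemble the plain-text report (dipole catalog, confusion matrix,
# accuracy metrics, ROC, restart robustness, signature summary). All metric
# values are re-derived from the pooled predictions, not cached.

library(ersplearn)

out <- "results"
res <- readRDS(file.path(out, "data", "pipeline.rds"))
rpt <- render_report(res)
writeLines(rpt, file.path(out, "report.md"))
hashes <- result_hashes(res)
writeLines(sprintf("%s\t%s", names(hashes), hashes),
           file.path(out, "hashes.tsv"))
cat(sprintf("report written to %s/report.md (%d lines)\n", out, length(rpt)))
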