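#!/usr/bin/env Rscript
# Stage 1: generate the synthetic swab study.
#
# Emits the full input file set (ASV counts, taxonomy, metadata, qPCR and
# environmental tables) for the default study shape: 7 algal tissues x 10
# months x 3 replicates with the two known deficit conditions (208 samples)
# plus 2 negative controls, and the planted ground truth used by stage 07.

library(qmpcore)

seed <- 2026
dir <- "results/fixture"
truth <- generate_truth(seed = seed)
paths <- write_fixture(truth, dir, seed = seed)

md <- truth$metadata
message(sprintf("design: %d samples over %d conditions, %d controls",
                sum(!md$is_negative_control),
                attr(enumerate_design(), "n_conditions"),
                sum(md$is_negative_control)))
message(sprintf("true loads span %.2e - %.2e copies/cm2",
                min(truth$loads), max(truth$loads)))
message(sprintf("taxa: %d ASVs in %d genera (%s)",
                nrow(truth$taxa), length(unique(truth$taxa$genus)),
                paste(names(table(truth$taxa$role)),
                      table(truth$taxa$role), collapse = ", ")))
message("wrote: ", paste(basename(paths), collapse = ", "), " -> ", dir)
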