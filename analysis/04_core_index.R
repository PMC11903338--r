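#!/usr/bin/env Rscript
# Stage 4: occupancy-redundancy core index.
#
# Computes the per-genus, per-tissue index (monthly occupancy + redundancy,
# scaled to a maximum of 1), averages the three Ldig blade parts into one
# host column and classifies core genera at the > 0.65 threshold on every
# host species.

library(qmpcore)

absg <- read_matrix_tsv("results/filter/absolute_genus.tsv")
md <- read_metadata("results/fixture/metadata.tsv")

idx <- core_index_table(absg, md, detection_threshold = 1e-9)
cls <- classify_core(idx, threshold = 0.65)

dir.create("results/core", showWarnings = FALSE, recursive = TRUE)
write_matrix_tsv(idx, "results/core/core_index.tsv", id_col = "genus")
write.table(
  data.frame(genus = rownames(cls$aggregated), cls$aggregated,
             core = cls$is_core, check.names = FALSE),
  "results/core/core_classification.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

message(sprintf("%d of %d genera are core (%d%% of genera):",
                length(cls$core), nrow(idx),
                whole_percent(length(cls$core), nrow(idx))))
message("  ", paste(cls$core, collapse = ", "))
ubiquitous <- rownames(idx)[apply(idx == 1, 1, all)]
message(sprintf("genera with index 1 on every tissue (present in all samples): %s",
                paste(ubiquitous, collapse = ", ")))
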