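#!/usr/bin/env Rscript
# Stage 3: filtering and absolute rescaling.
#
# Removes organellar/eukaryote ASVs, flags reagent contaminants from the
# negative controls (present in a control AND prevalence <= 11 samples AND
# max relative abundance <= 1.5%), rescales relative abundances by the
# qPCR loads into copies/cm2, and pools ASVs into genera.

library(qmpcore)

tab <- read_asv_table("results/fixture/asv_counts.tsv")
tax <- read_taxonomy("results/fixture/taxonomy.tsv")
md <- read_metadata("results/fixture/metadata.tsv")
loads <- read.delim("results/quantify/loads.tsv")

org <- remove_organellar(tab, tax)
message(sprintf("organellar filter removed %d ASVs", length(org$removed)))

controls <- md$sample_id[md$is_negative_control]
con <- flag_contaminants(org$table, controls)
message(sprintf("contaminant filter flagged %d ASVs (max freq %d, max relab %.2f%%)",
                length(con$flagged),
                if (nrow(con$report)) max(con$report$frequency) else 0,
                if (nrow(con$report)) 100 * max(con$report$max_relab) else 0))

absmat <- scale_to_absolute(con$table, loads)
pooled <- pool_by_rank(absmat, tax, "genus")
message(sprintf("absolute matrix: %d samples x %d ASVs; %d genera after pooling",
                nrow(absmat), ncol(absmat), ncol(pooled$matrix)))

dir.create("results/filter", showWarnings = FALSE, recursive = TRUE)
write.table(con$report, "results/filter/contaminant_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_matrix_tsv(absmat, "results/filter/absolute_asv.tsv",
                 id_col = "sample_id")
write_matrix_tsv(pooled$matrix, "results/filter/absolute_genus.tsv",
                 id_col = "sample_id")
rel <- sweep(unclass(con$table), 1, rowSums(con$table), "/")
write_matrix_tsv(pool_by_rank(rel, tax, "genus")$matrix,
                 "results/filter/relative_genus.tsv", id_col = "sample_id")
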