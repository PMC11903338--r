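#!/usr/bin/env Rscript
# Stage 5: host-specificity set analysis.
#
# Upset-style exclusive intersection counts over the five host species at
# the ASV and genus level, pairwise shared-ASV counts between samples, and
# the rank-based comparison of the intra-species / intra-phylum /
# inter-phylum pair classes (Kruskal-Wallis + pairwise Wilcoxon with BH).

library(qmpcore)

absa <- read_matrix_tsv("results/filter/absolute_asv.tsv")
absg <- read_matrix_tsv("results/filter/absolute_genus.tsv")
md <- read_metadata("results/fixture/metadata.tsv")

up_g <- intersection_counts(absg, md, detection_threshold = 1e-9)
up_a <- intersection_counts(absa, md, detection_threshold = 1e-9)
shared_all <- up_g$counts$n_taxa[up_g$counts$degree == 5]
message(sprintf("%d of %d genera (%d%%) detected on all 5 hosts",
                sum(up_g$membership %*% rep(1, 5) == 5), up_g$n_detected,
                whole_percent(shared_all, up_g$n_detected)))
single <- sum(up_a$counts$n_taxa[up_a$counts$degree == 1])
message(sprintf("%d of %d ASVs (%d%%) found on a single host",
                single, up_a$n_detected,
                whole_percent(single, up_a$n_detected)))

pairs <- pairwise_shared(absa, md)
cmp <- group_comparison(pairs)
message(sprintf("shared-ASV medians: %s",
                paste(names(cmp$medians), round(cmp$medians, 1),
                      sep = "=", collapse = ", ")))
message(sprintf("Kruskal-Wallis chi2(%d) = %.1f, p = %.3g",
                cmp$omnibus$df, cmp$omnibus$statistic, cmp$omnibus$p_value))

dir.create("results/specificity", showWarnings = FALSE, recursive = TRUE)
write.table(up_g$counts, "results/specificity/upset_genus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(up_a$counts, "results/specificity/upset_asv.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pairs, "results/specificity/shared_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cmp$pairwise, "results/specificity/pair_class_tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
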