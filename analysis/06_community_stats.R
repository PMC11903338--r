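#!/usr/bin/env Rscript
# Stage 6: community statistics.
#
# Bray-Curtis dissimilarities on the absolute ASV table, PERMANOVA by
# tissue and by season (999 permutations) with pairwise season
# comparisons, within-group dispersion, observed richness per tissue, and
# pruning of correlated environmental variables.

library(qmpcore)

absa <- read_matrix_tsv("results/filter/absolute_asv.tsv")
md <- read_metadata("results/fixture/metadata.tsv")
env <- read_env_table("results/fixture/env.tsv")
seed <- 2026

d <- bray_curtis(absa)
grp_t <- md$tissue[match(rownames(absa), md$sample_id)]
grp_s <- md$season[match(rownames(absa), md$sample_id)]

pt <- permanova(d, grp_t, n_perm = 999, seed = seed)
ps <- permanova(d, grp_s, n_perm = 999, seed = seed + 1)
message(sprintf("PERMANOVA tissue: F(%d,%d) = %.1f, R2 = %.2f, p = %.3f",
                pt$df[1], pt$df[2], pt$f, pt$r2, pt$p_value))
message(sprintf("PERMANOVA season: F(%d,%d) = %.1f, R2 = %.2f, p = %.3f",
                ps$df[1], ps$df[2], ps$f, ps$r2, ps$p_value))
pw <- pairwise_permanova(d, grp_s, n_perm = 999, seed = seed + 2)
disp <- dispersion(d, grp_t, n_perm = 199, seed = seed + 3)
message(sprintf("dispersion: F = %.2f, p = %.3f; group means %s",
                disp$f, disp$p_value,
                paste(names(disp$group_means),
                      round(disp$group_means, 3), sep = "=",
                      collapse = ", ")))
rich <- observed_richness(absa, groupby = grp_t,
                          detection_threshold = 1e-9)
ep <- env_prune(env)
message(sprintf("env pruning removed: %s; retained: %s",
                paste(ep$removed, collapse = ", "),
                paste(ep$retained, collapse = ", ")))

dir.create("results/stats", showWarnings = FALSE, recursive = TRUE)
write_matrix_tsv(d, "results/stats/bray_curtis.tsv", id_col = "sample_id")
write.table(
  data.frame(factor = c("tissue", "season"), f = c(pt$f, ps$f),
             df1 = c(pt$df[1], ps$df[1]), df2 = c(pt$df[2], ps$df[2]),
             r2 = c(pt$r2, ps$r2), p = c(pt$p_value, ps$p_value)),
  "results/stats/permanova.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
write.table(pw, "results/stats/pairwise_permanova_season.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rich$summary, "results/stats/richness.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ep$report, "results/stats/env_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
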