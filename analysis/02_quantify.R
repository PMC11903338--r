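#!/usr/bin/env Rscript
# Stage 2: qPCR quantification.
#
# Converts the per-reaction copy counts to total 16S rRNA gene copies per
# cm2 of algal surface (N = n*C*V / (c*v*S)) and summarises the loads per
# tissue, flagging undiluted extracts and implausible values.

library(qmpcore)

md <- read_metadata("results/fixture/metadata.tsv")
qp <- read_qpcr("results/fixture/qpcr.tsv")
loads <- attach_loads(md, qp)

dir.create("results/quantify", showWarnings = FALSE, recursive = TRUE)
write.table(loads, "results/quantify/loads.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("N spans %.2e - %.2e copies/cm2 (undiluted extracts: %d,",
                min(loads$N), max(loads$N), sum(loads$undiluted)))
message(sprintf("  implausible: %d)", sum(loads$implausible)))
by_tissue <- tapply(loads$N, md$tissue[match(loads$sample_id, md$sample_id)],
                    mean)
for (tt in names(by_tissue)) {
  message(sprintf("  mean load on %-6s %.2e copies/cm2 (~%.1e cells/cm2)",
                  tt, by_tissue[tt], copies_to_cells(by_tissue[tt])))
}
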