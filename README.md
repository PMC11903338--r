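# qmpcore

Quantitative profiling of host-associated microbiota from surface swabs,
with qPCR-anchored absolute abundances and occupancy–redundancy core-taxon
detection.

## The problem

16S rRNA gene metabarcoding yields *relative* abundances: an apparent
increase of one taxon can be nothing but the decrease of another, or a
change in total microbial load. For surface-associated communities — here,
the epiphytic bacteria of intertidal macroalgae sampled by standardised
swabbing — this compositional artifact is acute, because total bacterial
density itself varies by orders of magnitude across hosts and seasons.

`qmpcore` implements quantitative microbiome profiling (QMP) for such swab
studies. The total number of 16S rRNA gene copies per cm² of swabbed
surface is estimated by qPCR, undoing the normalisation of the DNA extract:

    N = n · C · V / (c · v · S)

where *n* is the copies detected in the reaction, *C* the original extract
concentration (ng·µL⁻¹), *V* the extract volume (µL), *c* the normalised
input concentration (ng·µL⁻¹), *v* the input volume (µL) and *S* the
swabbed surface (cm²). Each sample's relative ASV abundances are then
multiplied by its *N*, giving a table of absolute copy densities
(copies·cm⁻²) on which all downstream statistics run. Copy densities
convert to cell densities by dividing by the rRNA operon number per genome
(3 by default).

On top of the quantitative scaling, the package provides:

- **Filtering** — removal of organellar/eukaryote ASVs (cyanobacteria
  incl. chloroplasts, mitochondria, Eukaryota) and of reagent contaminants
  identified from negative controls (present in a control, prevalence ≤ 11
  samples, max relative abundance ≤ 1.5%; all thresholds configurable).
- **Core-taxon detection** — a per-taxon, per-tissue occupancy–redundancy
  index. For each month, the occupancy term is the fraction of replicate
  swabs where the taxon is detected and the redundancy term is 1 iff it is
  detected in *all* replicates. The index is the sum of both terms over
  months scaled by its theoretical maximum `2 · n_months`, so it lives in
  [0, 1] and equals 1 exactly for a taxon present in every sample. Taxa
  with index > 0.65 on every host species are classified core.
- **Host specificity** — upset-style exclusive intersection counts across
  hosts, and shared-ASV comparisons between intra-species, intra-phylum
  and inter-phylum sample pairs (Kruskal–Wallis + pairwise Wilcoxon, BH).
- **Community statistics** — Bray–Curtis dissimilarities, single-factor
  PERMANOVA with permutation p-values (`(1 + #{F_perm ≥ F_obs}) / (1 + P)`),
  pairwise PERMANOVA with BH adjustment, multivariate dispersion via
  principal-coordinate embedding, observed richness, and greedy pruning of
  correlated environmental variables.
- **A synthetic-data generator** — a seeded simulator of the full study
  design (7 algal tissues × 10 months × 3 replicates with two known
  replicate deficits, 208 samples, negative controls) with planted core,
  host-specific, seasonal, background, organellar and contaminant taxa and
  a known ground truth, used by the recovery tests.

## Worked example

The `analysis/` directory is a numbered, file-based workflow over the
package. Running it end to end:

```sh
Rscript analysis/01_simulate.R      # synthetic study -> results/fixture/
Rscript analysis/02_quantify.R      # qPCR -> copies/cm2
Rscript analysis/03_filter_scale.R  # filters + absolute scaling
Rscript analysis/04_core_index.R    # occupancy-redundancy index
Rscript analysis/05_specificity.R   # upset counts, shared-ASV tests
Rscript analysis/06_community_stats.R
Rscript analysis/07_recovery.R      # score against the planted truth
```

prints, among other things:

```
design: 208 samples over 70 conditions, 2 controls
organellar filter removed 5 ASVs
contaminant filter flagged 10 ASVs (max freq 8, max relab 0.40%)
11 of 107 genera are core (10% of genera)
PERMANOVA tissue: F(6,201) = 10.9, R2 = 0.25, p = 0.001
PERMANOVA season: F(2,205) = 46.4, R2 = 0.31, p = 0.001
core detection: precision 1.00, recall 1.00
constant-load taxon, summer/winter fold change: 1.02 quantitative vs 0.22 relative-only
```

The last line is the point of quantitative profiling in one number: a
taxon whose absolute density never changes appears to drop ~5-fold in
relative abundance when the total load rises ~5-fold with season; the
qPCR-anchored estimate correctly reads it as flat (fold change ≈ 1).

Programmatic use mirrors the scripts:

```r
library(qmpcore)
truth <- generate_truth(seed = 1)
paths <- write_fixture(truth, "fixture")
manifest <- run_pipeline(list(
  inputs = as.list(paths[c("asv", "taxonomy", "metadata", "qpcr")]),
  out_dir = "out"
))
res <- attr(manifest, "results")
res$core$classified$core          # genera above the core threshold
res$stats$permanova_tissue        # pseudo-F, R2, permutation p
```

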