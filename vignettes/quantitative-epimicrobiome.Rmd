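---
title: "Quantitative profiling and core detection for swab-sampled microbiota"
author: "qmpcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative profiling and core detection for swab-sampled microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmpcore)
```

## The model

Amplicon sequencing of the 16S rRNA gene returns compositions: per-sample
read counts whose total is an artifact of library preparation, not of the
community. Any statement about a taxon "increasing" therefore confounds
three things — the taxon's own density, the density of everything else,
and the total microbial load. Quantitative microbiome profiling (QMP)
breaks the confound by measuring total load independently. Here the load
is the total number of 16S gene copies per cm² of swabbed host surface,
estimated by qPCR on the same DNA extract used for sequencing:

$$N = \frac{n \cdot C \cdot V}{c \cdot v \cdot S}$$

with $n$ the copies detected in the reaction, $C$ the extract
concentration before normalisation (ng·µL⁻¹), $V$ the extract volume
(50 µL), $c$ the normalised input concentration (0.5 ng·µL⁻¹), $v$ the
input volume (1.5 µL) and $S$ the swabbed surface (50 cm²). The formula
simply undoes the dilution that equalised qPCR inputs; with the default
constants it reduces to $N = \tfrac{4}{3} n C$. Extracts already below the
normalisation target are used undiluted, in which case $c = C$ and
$N = nV/(vS)$; `attach_loads()` flags this path rather than hiding it.
Each sample's relative ASV abundances are multiplied by its $N$
(`scale_to_absolute()`), giving copies·cm⁻² whose row sums equal $N$ by
construction. Dividing by the rRNA operon number per genome (default 3,
the count in the reference *Granulosicoccus antarcticus* genome) converts
copies to approximate cell densities.

Two read-level filters precede the scaling. Organellar and eukaryote
sequences (cyanobacteria including chloroplasts, mitochondria, Eukaryota
— host plastids amplify with universal primers) are removed by lineage
label at any rank. Reagent contaminants are identified from negative
controls with a three-clause rule: present in at least one control, AND
prevalence among real samples at most `max_freq` (default 11 of 208), AND
maximum per-sample relative abundance at most `max_relab` (default 1.5%).
These bounds are descriptive of a particular study system, not universal
constants, so they are explicit configuration.
Relative abundance for this filter is computed on reads (controls have no
qPCR load). The clauses are evaluated on the post-organellar-filter table;
because the predicate is then a fixed property of each column, the two
filters commute, which the test suite asserts.

## The occupancy–redundancy index

Core taxa are those consistently present across replicates and months.
For one tissue, build the presence/absence cube (taxon × month ×
replicate; a replicate slot missing from the design is `NA`, not absence).
For each month $m$,

- occupancy $O_m$ = mean presence over non-missing replicates,
- redundancy $R_m$ = 1 iff present in every non-missing replicate.

The index is $\sum_m (O_m + R_m) / (2 M)$ over the $M$ sampled months.
The denominator is the *theoretical* maximum, so an always-present taxon
scores exactly 1 and an always-absent one 0; the index is monotone in
presence. A taxon is core iff its index strictly exceeds the threshold
(default 0.65) on **every** host species, where the three *Laminaria
digitata* blade parts are first averaged into a single host column. Ties
at the threshold are non-core.

Three decisions here were genuinely open. (1) In the two deficit months
with only two swabs, redundancy uses "all available replicates": a
missing swab is missing data and should not cap a consistently present
taxon below 1. (2) The scaling denominator is the theoretical maximum
rather than the observed one, so index = 1 retains its plain reading
(present in all samples). (3) The 0.65 default threshold is an empirical
calibration against observed index distributions, not derivable from
first principles, so it stays a parameter; the recovery tests show planted
always-present taxa are recovered exactly at this value, and taxa with
per-sample presence probability ≤ 0.5 stay far below it.

## Host specificity and community statistics

Detection for set membership is at least one read on any sample of a
host; exclusive intersection counts over the $2^5 - 1$ host subsets are
the numbers an upset plot displays. Shared-ASV counts between sample
pairs are classified intra-species (same brown-algal host), intra-phylum
(different brown hosts) or inter-phylum (brown vs red/green host); pairs
entirely within the non-brown hosts fit none of the three classes and are
excluded. The class comparison is a Kruskal–Wallis test followed by
pairwise Wilcoxon tests with Benjamini–Hochberg adjustment (both from
base R's `stats`, as any practitioner would).

The distance machinery is written in the package and cross-checked in the
tests against `vegan`, which serves as an independent oracle and never as
the implementation. Bray–Curtis is $\sum_i |x_i - y_i| / \sum_i (x_i +
y_i)$, computed on the *absolute* abundance table. PERMANOVA partitions
squared dissimilarities, $SS_{tot} = \tfrac{1}{N}\sum_{i<j} d_{ij}^2$ and
$SS_w = \sum_g \tfrac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$, forms the
pseudo-F with $(k-1, N-k)$ degrees of freedom, and permutes whole-sample
labels. The p-value uses the add-one convention, so its support is
$\{1/(P+1), \dots, 1\}$ and it is never zero; all permutation draws are
seeded and bit-reproducible. Dispersion embeds the distance matrix by
principal coordinates, keeping negative-eigenvalue axes as imaginary
coordinates whose squared contributions are subtracted (truncated at zero
before the square root), which reproduces planar geometry to 1e-8 on
Euclidean-embeddable inputs.

Environmental pruning removes, greedily by largest offending |r|,
variables whose pairwise Pearson correlation has BH-adjusted p < 0.05 and
|r| ≥ 0.8. Manual variable selection in published analyses is rarely
algorithmic; the greedy rule is one defensible automation, and the full
correlation report is returned so the choice is auditable. Constant
variables have undefined correlations and are flagged, not removed.

## What the synthetic generator emulates

`generate_truth()` draws the complete study: 7 tissues × 10 sampled
months (April and May are absent by design) × 3 replicates, with exactly
two conditions reduced to 2 replicates (208 samples), plus 2 negative
controls. Default parameters were fixed once, on the scale of the system
being emulated:

- **Loads**: log-normal, winter median 2×10⁶ copies·cm⁻², log-sd 0.5,
  clamped to [1×10⁵, 5×10⁷] (the observed range spans two orders of
  magnitude), with seasonal multipliers winter 1×, summer 5×, autumn 2×
  reflecting the late-summer/autumn density peak; the resulting year-round
  mean sits near 7×10⁶ copies·cm⁻².
- **Roles**: 10 core genera (always present, dominant weight, two of them
  split over two ASVs to exercise genus pooling); 2 host-specific genera
  per host (zero weight off-host); 6 seasonal genera with a 5-fold peak
  and presence probability 0.4 off-season; 80 sparse background genera
  (presence probability 0.5); 5 organellar ASVs (chloroplast lineage,
  removed by the filter); 10 contaminants present in the controls and
  intruding into at most 8 real samples at ~0.3% relative abundance —
  inside the contaminant rule's bounds by construction; and one
  constant-absolute-load taxon (2×10⁵ copies·cm⁻² everywhere).
- **Noise**: log-normal replicate noise (log-sd 0.3), fixed per-host
  abundance multipliers (log-sd 0.8) so hosts differ in composition and
  not only in their private taxa, multinomial read sampling at depth
  20,000 (2,000 for controls), and log-normal qPCR noise (log-sd 0.1).
  All positive quantities are log-normal, matching the long-tailed
  abundance distributions of real amplicon data.

The constant-load taxon against the seasonal load gradient is the
generator's built-in demonstration of the compositional artifact: its
quantitative summer/winter fold change estimates ≈ 1 while the
relative-only estimate is ≈ 0.2.

What the generator does **not** emulate: sequence-level error (no FASTQ,
no chimeras), PCR primer bias, taxonomic misassignment, overdispersed
(non-multinomial) read sampling, and spatial structure within a blade.
Passing recovery tests therefore show that the pipeline's logic is
correct under its own statistical assumptions, not that those assumptions
hold for any particular real data set.

## Numerical choices and problem sizes

Row-sum identities are asserted to 1e-6 relative tolerance; TSV writers
serialise floats at 12 significant digits with "." as decimal separator
regardless of locale, so write/read round-trips are stable. Degenerate
inputs fail loudly: samples with zero reads but positive load are
"unresolvable", months with no replicates are errors, an all-identical
distance matrix yields an undefined dispersion F with a warning rather
than an arbitrary number. Missing taxonomy ranks are empty strings, never
the text "NA".

The test suite runs the pipeline on the full 208-sample fixture with
reduced permutation counts (19–99), calibrates the PERMANOVA null on
1,000 simulated 12-sample data sets at 99 permutations each, and checks
the N = 6 permutation p-value against exhaustive enumeration over all 20
balanced label assignments; these sizes keep the suite under a minute
while leaving each check statistically sharp. The analysis scripts use
999 permutations, matching standard practice.

## Limitations

The qPCR anchor inherits swab-sampling biases (surface saturation,
extraction efficiency, unequal lysis) that no downstream arithmetic can
undo, and qPCR and sequencing primers cover slightly different taxon
sets. Copy-to-cell conversion assumes a single operon number across taxa.
The core threshold and the contaminant bounds are study-calibrated
parameters, not discoveries of this package. PERMANOVA here is
single-factor with raw-label permutation; factorial designs and
residual-permutation schemes are out of scope, as are ordination (NMDS,
dbRDA) and differential-abundance modelling, for which the exported
distance matrices and absolute tables are the intended inputs.
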