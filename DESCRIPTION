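Package: qmpcore
Title: Quantitative Profiling and Core-Taxon Detection for Host-Associated Microbiota
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for qPCR-anchored quantitative microbiome profiling of
    surface-swab amplicon data: conversion of qPCR measurements to total 16S
    rRNA gene copies per cm2, organellar and negative-control contaminant
    filtering, rescaling of relative ASV abundances to absolute copy
    densities, an occupancy-redundancy index for core-taxon detection,
    host-specificity set analysis, and permutation-based community statistics
    (Bray-Curtis, PERMANOVA, multivariate dispersion). Includes a seeded
    synthetic-data generator that emulates a multi-host, multi-month swab
    study design with planted core, host-specific, seasonal and contaminant
    taxa for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
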