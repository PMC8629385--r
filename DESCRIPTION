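Package: devomap
Title: Comparative Developmental Transcriptome Alignment and Population-Genomic Sweep Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing developmental time-course transcriptomes
    between two conditions (breeds, strains, species) and for scanning two
    populations for selective sweeps. The core method aligns two time courses
    by calling development-associated genes (DAGs) per time point, scoring
    every time-point pair with a -log10 Bonferroni-corrected hypergeometric
    overlap P-value, and extracting the maximum-scoring monotone trace through
    the score matrix by dynamic programming; deviations of the trace from the
    diagonal quantify developmental lead or lag. Supporting layers include
    expression summary statistics and classical MDS ordination, Welch and
    regression-based differential-expression tests with Benjamini-Hochberg
    control, phase-specific gene calling, CV-filtered k-means co-expression
    modules with figure-of-merit model selection, competing-endogenous-RNA
    (lincRNA-miRNA-mRNA) triplet network construction from seed matches and
    expression correlations, and a windowed Weir-Cockerham FST plus
    nucleotide-diversity-ratio selective-sweep scan with empirical-quantile
    thresholds. Synthetic-data generators with known ground truth (injected
    developmental lag, trajectory archetypes, miRNA-target anticorrelation,
    Balding-Nichols population structure with injected sweeps) support
    calibration and recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
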