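Package: hapscan
Title: Haplotype Selection Scans and Temporal Population Genomics for
    Vector Surveillance Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genomic analysis of phased biallelic SNP
    data from structured field cohorts, aimed at insecticide-resistance
    surveillance in malaria vectors. Implements Garud's haplotype
    homozygosity statistics (H1, H12, H123, H2/H1) and the cross-cohort
    H1X statistic in SNP-count windows, genome-wide scans with top-quantile
    thresholding and peak calling, a pre/post-intervention delta-H12
    contrast with a label-permutation significance test, nucleotide
    diversity, Watterson's theta and Tajima's D, Hudson and Patterson F_ST
    estimators with a two-individual resampling null and Mann-Whitney
    comparison, PCA and neighbour-joining trees, complete-linkage
    diplotype clustering at candidate loci, and a per-SNP temporal
    association test with household-cluster-robust variance and FDR
    control. A synthetic cohort generator emulating a two-region,
    two-round, two-arm cluster-randomised trial design (neutral 1/i site
    frequency spectrum, injected hard/soft sweeps, household effects,
    weak regional differentiation) makes the full pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
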