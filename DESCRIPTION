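Package: radscan
Title: Genome Scans for Parallel Ecomorph Divergence and Introgression in
    Lake Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed genome scans for detecting parallel divergence between
    ecomorph groups across replicate lake populations: cluster separation
    score (CSS) scans with a lake-stratified permutation null and FDR outlier
    calling, windowed Weir-Cockerham FST outlier scans with analytic
    cross-lake overlap expectations, four-taxon F4 topology contrasts,
    tree-guided excess allele-sharing statistics (Patterson's D, f4-admixture
    ratio, f-branch) with block-jackknife Z-scores, and GWAS support
    computations (multiple-testing thresholds, per-SNP variance explained).
    Includes an admixture-aware synthetic radiation generator so every stage
    can be exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    ape,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
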