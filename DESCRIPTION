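Package: laspa
Title: Local Ancestry Summation Partition Approach for Region-Based
    Rare-Variant Scans in Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Region-based genome scan for quantitative traits in recently
    admixed cohorts. Genotypes are adjusted for covariates and global
    ancestry (first principal component), split into fixed-size windows of
    consecutive variants, and each window is stratified into common and
    rare variants by minor allele frequency. Local ancestry within a window
    is inferred by principal component analysis of the common variants
    followed by k-means clustering, and rare-variant association is tested
    with the summation partition approach (SPA) statistic and its
    local-ancestry partitioned extension (LA-SPA), with significance
    assessed by a two-level permutation scheme. Includes a Balding-Nichols
    admixed-cohort simulator with block-wise local ancestry for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, Genetics, StatisticalMethod,
    VariantAnnotation
RoxygenNote: 7.3.3
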