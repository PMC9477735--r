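Package: hapscreen
Title: Analysis of Haploid Gene-Trap Genetic Screens
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Enrichment analysis for phenotype-sorted haploid gene-trap
    mutagenesis screens. Maps unique sense-orientation gene-trap insertion
    sites onto gene bodies, builds per-gene 2x2 contingency tables between
    high- and low-reporter sorted populations, computes two-sided Fisher's
    exact tests with Benjamini-Hochberg false-discovery-rate correction,
    and derives the mutation-ratio/combined-count ("fishtail") coordinates
    used to call pathway regulators. Includes a seeded screen simulator
    with known ground truth (FACS-style quantile sorting of a log-normal
    reporter), a co-expression partner selection procedure over
    gene-by-tissue expression atlases, and small assay statistics:
    relative response ratio normalization for split-luciferase
    complementation and four-parameter logistic EC50 fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
biocViews: FunctionalGenomics, Software, StatisticalMethod, PooledScreens
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'assay.R'
    'coexpression.R'
    'enrichment.R'
    'hapscreen-package.R'
    'mapping.R'
    'methods.R'
    'simulate.R'
    'utils.R'
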