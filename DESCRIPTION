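Package: mseqith
Title: Multi-Region Tumour Sequencing Intratumoural Heterogeneity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-region tumour sequencing studies:
    cancer cell fraction (CCF) estimation and binomial-mixture clustering of
    somatic mutations into subclones, clone-tree reconstruction with
    parallel-evolution detection, SNV and copy-number intratumoural
    heterogeneity metrics (ubiquitous/shared/private classification, fraction
    of genome altered, heterogeneous SCNA fraction, whole-genome doubling),
    burden-controlled locus enrichment tests, mutational-signature
    attribution by clonality, and genotype-immune-infiltrate association
    tests. Includes a synthetic multi-region cohort generator with known
    clonal structure so every inference stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
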