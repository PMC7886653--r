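Package: polyadapt
Title: Polyploid Climate-Adaptation Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for climate-adaptation genomics in polyploid
    plant panels: k-mer based duplicate-haplotype purging and subgenome
    assignment, allele-balance ploidy calling, Weir-Cockerham FST and
    ancestry-informative marker selection, LD-decay estimation, DAPC-style
    clustering and eigenvector ancestry coefficients, a relative
    cross-coalescence divergence rule, a two-ancestry pulse-model local
    ancestry HMM with pulse dating, AI-REML regional-heritability variance
    partitioning (including an 18-matrix chromosome-by-subgenome partition),
    and GWAS-region adaptation scans with redundancy-analysis variance
    partitioning. Ships a synthetic-data module that generates inputs with
    the statistical structure each stage assumes, so the full pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    cluster,
    MASS,
    vegan,
    minpack.lm,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    Biostrings,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
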