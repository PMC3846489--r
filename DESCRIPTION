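Package: hdimpute
Title: Accuracy of High-Density Genotype Imputation in Pedigreed Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for studying the accuracy of
    imputation from a medium-density (50K-like) SNP panel to a high-density
    panel in pedigreed livestock populations. Provides a pedigree gene-drop
    simulator with tunable linkage disequilibrium and family structure,
    SNP-array quality control (call-rate, exact Hardy-Weinberg, cross-chip
    concordance, opposing-homozygote parentage testing and Mendelian repair),
    a haplotype-copying hidden Markov model for phasing and imputation,
    allelic imputation error rates overall, per animal and per SNP, detection
    of mismapped SNPs from recurrently high per-SNP error across breeds,
    linkage-disequilibrium decay from phased haplotypes, pedigree numerator
    relationships and effective numbers of ancestors, and a multiple
    regression of breed-level error rates on population factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    Rcpp,
    readr,
    stats,
    tibble,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
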