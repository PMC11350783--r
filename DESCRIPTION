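Package: wssgblup
Title: Weighted Single-Step GBLUP and SNP-Window Association Analysis
Version: 0.1.0
Authors@R: person("PRE", "Genomics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for weighted single-step genomic BLUP (wssGBLUP) analysis of
    quantitative and ordinal-scored traits in pedigreed populations: pedigree
    validation, inbreeding and numerator relationship matrices with sparse
    inverses, PLINK genotype input and call-rate quality control, VanRaden
    genomic relationship matrices with SNP weighting, single-step H-inverse
    assembly, multivariate animal-model REML (EM and average-information
    algorithms), back-solving of genomic breeding values to SNP effects,
    iterative SNP re-weighting, and 1-Mb sliding-window scans of the
    percentage of additive genetic variance with significance-region
    selection. Includes a gene-dropping simulator of pedigrees, genotypes and
    correlated zero-inflated ordinal phenotypes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
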