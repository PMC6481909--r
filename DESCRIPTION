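Package: expansionr
Title: Range Expansion Inference from Polarized SNP Directionality
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the geographic origin of a population range expansion from
    biallelic SNP genotypes. Polarizes alleles against an outgroup, computes the
    pairwise directionality index (psi) on shared derived polymorphisms, locates
    the most likely expansion origin with a time-difference-of-arrival grid
    search over geography, and tests the expansion signal against an
    isolation-by-distance null by coordinate permutation. Includes classical
    principal coordinates analysis for geographic grouping, per-population
    heterozygosity, GBS-style SNP filtering and subsetting schemes, and a
    forward-time serial-founder simulator (allele surfing, stepping-stone
    isolation-by-distance nulls, outgroup divergence, missing data) for
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
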