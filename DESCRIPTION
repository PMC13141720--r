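Package: chipconcord
Title: Cross-Platform Concordance of Population-Genetic Inference from
    SNP Chips and Dense Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates how faithfully a reduced, MAF-ascertained SNP panel
    (a "chip") reproduces population-genetic inference from a dense
    genotype panel on the same individuals. Provides VCF genotype input
    and output with quality-control and LD-pruning filters, a seeded
    Balding-Nichols simulator of structured breeding lines with chip
    ascertainment, diversity statistics (Ho, He, MAF, windowed nucleotide
    diversity), windowed Weir-Cockerham FST, locus-specific branch length
    (LSBL) and joint FST-pi selection scans, population-structure
    inference (Patterson-scaled PCA, neighbor-joining trees with
    bootstrap, an EM admixture model with cross-validation over K), and
    quantitative cross-platform concordance reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
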