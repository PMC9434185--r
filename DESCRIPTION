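Package: rhogc
Title: Coestimating Crossover and Gene-Conversion Rates from Diploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Composite-likelihood coestimation of the population-scaled
    crossover rate (kappa = 4Nc), gene-conversion initiation rate
    (gamma = 4Ng) and mean gene-conversion tract length (L) from the
    distance-dependent pattern of two-locus heterozygosity in unphased
    diploid genomes. Includes the full pipeline: extraction of per-distance
    two-locus zygosity-state counts from VCF genotypes within BED intervals,
    per-distance rho profiling, per-chromosome and joint multi-chromosome
    fits with a shared tract length, composite-likelihood surfaces, and a
    synthetic-data / parametric-bootstrap harness (multinomial sampling and,
    optionally, coalescent simulation with gene conversion).
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    rlang,
    stats,
    utils,
    lhs,
    jsonlite,
    generics
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
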