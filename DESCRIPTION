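Package: sweepscan
Title: Selection-Sweep Scans for Multi-Population SNP Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to detect genomic regions under directional selection from
    multi-population biallelic SNP genotypes. Provides PLINK-text (PED/MAP)
    input with SNP quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test), population-structure summaries
    (identity-by-state distances, classical multidimensional scaling,
    Reynolds distances, neighbor-joining trees and tree-derived kinship),
    a Bayesian FST-outlier scan using a logistic decomposition of FST into
    locus and population effects with reversible-jump MCMC, the FLK and
    hapFLK haplotype-differentiation statistics built on a haplotype-cluster
    hidden Markov model fitted by EM, sweep-region calling, and a circular
    permutation test of overlap between sweep interval sets. A synthetic-data
    generator simulates tree-structured drift with injected selection for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    ape,
    phangorn,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
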