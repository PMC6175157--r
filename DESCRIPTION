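Package: sirescan
Title: Genome Scans and Gene-Set Enrichment for Sire Fertility Traits
Version: 0.1.0
Authors@R:
    person("Sirescan", "Developers", email = "sirescan@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of service-sire
    fertility evaluations such as sire conception rate (SCR). Implements a
    reliability-weighted single-step genomic BLUP (ssGBLUP) repeatability
    animal model with the combined pedigree-genomic relationship matrix H,
    back-solution of SNP effects from genomic breeding values, and a
    1.5-Mb sliding-window scan of additive genetic variance; a two-step
    mixed-model genome scan for dominance, recessive and overdominance
    effects with genomic control and Bonferroni thresholding; and
    hypergeometric gene-set enrichment of genes flagged by top-ranked SNP
    effects. A synthetic-data module generates pedigrees, genotypes,
    quantitative-trait architectures and repeated phenotype records with
    known truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
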