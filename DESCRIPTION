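Package: herdscan
Title: Pileup-Based Diversity, Runs of Homozygosity, f3 Admixture Tests
    and LD-Based Effective Population Size for Livestock Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population-genomics toolkit for individual whole-genome
    resequencing and SNP-array data from livestock. From per-site pileup
    tables it computes windowed heterozygosity, co-estimates the population
    mutation rate (theta) and the sequencing error rate (epsilon) by maximum
    likelihood, and calls runs of homozygosity (ROH) with a bin-based
    seed-and-extend algorithm, reporting nucleotide diversity inside and
    outside ROH. From diploid genotype matrices it performs missingness and
    minor-allele-frequency QC, windowed LD pruning, three-population f3
    admixture tests with block-jackknife standard errors, and LD-decay-based
    effective-population-size trajectories. A synthetic-data module generates
    pileup genomes with planted ROH, Balding-Nichols admixed allele-frequency
    panels, and two-locus Wright-Fisher populations so that every estimator
    is verifiable by parameter recovery against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
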