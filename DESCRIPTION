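Package: sweepscan
Title: Selection-Signature Scans and Diversity Analysis for Multi-Population SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic statistics (nucleotide diversity,
    Weir-Cockerham FST, pooled heterozygosity, Tajima's D) over sliding
    genomic windows, Z-normalized multi-method selective-sweep detection with
    empirical tail thresholds, candidate-region merging, gene annotation and
    three-method intersection, plus a diversity/structure layer (runs of
    homozygosity, LD decay and pruning, genotype PCA, identity-by-state
    distances and neighbor-joining trees).  Includes seeded synthetic-data
    generators (Balding-Nichols and forward Wright-Fisher with hard sweeps)
    so the whole pipeline is testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
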