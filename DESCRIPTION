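Package: tadadiff
Title: Targeted DamID Differential Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for Targeted DamID (TaDa) data: builds the GATC
    fragment coordinate system by in-silico DpnI digestion, forms normalized
    log2(Dam-fusion/Dam) ratio tracks, calls transcript- and gene-level
    occupancy with an empirical permutation FDR, compares genotypes by
    replicate-wise track subtraction with a numerator-occupancy filter,
    applies a Polycomb binding-loss filter, and computes the categorical
    phenotype statistics (two-tailed Fisher exact tests, Wilson score
    intervals) used alongside such profiling experiments. A synthetic-data
    module generates genomes, annotations and negative-binomial DamID counts
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
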