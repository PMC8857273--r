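Package: silencerscope
Title: Genome-Wide Characterisation of Xenogeneic Silencer Targetomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the binding targetome of bacterial
    xenogeneic silencers (H-NS/Lsr2/MvaT/Rok/MucR-type nucleoid-associated
    proteins) from called ChIP-seq peaks. Consolidates peaks across
    replicates and conditions by single-linkage summit clustering, assigns
    peaks to target genes through promoter windows, scans genomes for a
    degenerate flexible motif with periodic T repeats under per-region
    indel tolerance, computes zero-order-Markov oligonucleotide usage
    deviations and per-word binding preferences, builds and scans paired
    -35/-10 promoter models with spacer composition statistics, and
    integrates targets with hierarchical pangenome conservation classes.
    Includes a fully seeded synthetic-data generator with a ground-truth
    ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    yaml
Config/testthat/edition: 3
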