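Package: viromics
Title: Post-Assembly RNA Virome Profiling from Transcriptomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising RNA viruses discovered in host
    transcriptome assemblies: screening contigs for viral candidates from
    BLAST and HMMER evidence tables (RdRp-domain route, host-genome
    subtraction, identity clustering, completeness classification),
    quantifying viral read abundance and COI-based sample contamination
    from alignments, calling low-frequency variants to detect
    ADAR-compatible A-to-G editing footprints with 5'-neighbour
    annotation, a codon-preserving third-position permutation test for
    dinucleotide under-representation ("below" and "repTrFrac" metrics),
    and small-RNA size-profile diagnostics separating RNAi products from
    degradation fragments. A synthetic-data generator emulates every
    input so all stages are testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
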