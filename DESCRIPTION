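Package: meatseq
Title: Identification of Animal-Derived Components in Meat by Mitochondrial
    Amplicon Sequencing
Version: 0.1.0
Authors@R: person("meatseq", "developers", role = c("aut", "cre"),
    email = "meatseq@example.org")
Description: Toolkit for detecting animal species in mixed meat products from
    high-throughput sequencing reads. Builds a category-curated mitochondrial
    genome reference database, defines marker amplicons by in-silico PCR with
    universal primers (CYTB, COI, D-loop presets), maps amplicon or shotgun
    reads with an internal k-mer seed-and-extend aligner or ingests external
    SAM alignments, assigns each read to a single meat category by the
    unique-read rule, and reports per-category read counts, proportions,
    differences against a target composition, qualitative presence calls and
    concordance with a reference method. Includes seeded FASTQ subsampling
    with relative-standard-deviation summaries for sequencing-throughput
    optimisation, a neighbor-joining marker phylogeny with a category
    monophyly check, and a deterministic synthetic-data generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
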