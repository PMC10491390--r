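Package: virotax
Title: Viral Contig Triage and Taxonomic Classification with Calibrated
    Marker Profile HMMs
Version: 0.1.0
Authors@R:
    person("Virotax", "Developers", email = "virotax@example.org",
           role = c("aut", "cre"))
Description: Tools for the taxonomic characterisation of viral contigs in
    metagenomic assemblies using taxon-informative protein profile HMMs.
    Includes calibration of per-model bit-score cutoffs (GA/TC/NC) from
    homology-search hit tables, taxon-specific marker-to-CDS ratio (TSR)
    statistics, evidence-based triage of contigs into high-confidence,
    low-confidence and putative-prophage sets, a rank-escalating taxonomic
    voting classifier, an alignment-based benchmarking scheme
    (precision/recall/F1 against genome-alignment truth labels), and
    deterministic synthetic-fixture generators so the full workflow is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
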