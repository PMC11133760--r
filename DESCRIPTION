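Package: barkit
Title: Cellular Barcoding Extraction, Quantification and Clonal Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end processing of cellular (lineage) barcoding sequencing
    data at population, single-cell and spatial resolution. Extracts variable
    lineage barcodes from raw reads by constant-region trimming with
    quality and complexity filtering, quantifies them against a reference
    library of known barcodes or by reference-free Levenshtein clustering,
    handles cell barcodes and UMIs including PCR-chimera removal and UMI
    collapsing, and provides downstream clonal analysis: depth and count
    filters, replicate handling, CPM/percent/TMM normalisation, diversity
    indices (Shannon, Simpson, inverse Simpson, Gini) and hypergeometric
    clone-in-cluster enrichment. Ships a seeded synthetic-data generator
    emitting FASTQ/SAM reads with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    Rsamtools,
    edgeR,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
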