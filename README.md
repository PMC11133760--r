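# barkit

Cellular barcoding — tagging clones with heritable synthetic DNA barcodes
and reading them out by sequencing — is a workhorse of lineage tracing in
cancer biology, stem-cell research and clonal evolution studies. Between
the sequencer and any biological conclusion sit two non-trivial steps:
extracting the variable barcode from raw reads (through staggers, constant
flanking regions, sequencing errors, cell barcodes and UMIs) and turning
the resulting counts into defensible clonal statistics. `barkit` is an R
toolkit for both, aimed at labs running population-level barcode-seq,
single-cell expressed-barcode amplicons, or spatially resolved capture
data.

## What it does

**Extraction and quantification.** Reads are merged (paired-end), filtered
by Phred quality (`pctqual`% of bases ≥ `minqual`) and sequence complexity
(% of adjacent bases that differ), and trimmed at user-defined constant
regions with a substitution-only matcher that supports partial anchors at
read ends, five flanking modes and an explicit barcode length policy.
Quantification is either **reference-based** — Hamming assignment
(≤ 3 mismatches, prefix/suffix-anchored for short reads, ambiguous hits
discarded) against a library of known barcodes — or **reference-free**,
by greedy Levenshtein sphere clustering gated by a count ratio
(centroid count ≥ ratio × member count within distance *d*).

**Single-cell and spatial.** Cell barcode + UMI parsing from a `C/N`
pattern, whitelist filtering with optional 1-mismatch correction, knee
cell calling, PCR-chimera removal (per (cell, UMI), only the lineage
barcode with strictly maximal read support survives; ties are removed),
directional-network UMI collapsing, UMI-count and dominant-fraction
filters, comma-separated per-cell annotation, and aggregation of
coordinate-tagged spots into square bins.

**Clonal analysis.** Sample-depth percentile filters, absolute/relative
count thresholds, replicate correlation and collapsing, CPM / percentage /
TMM normalisation, the number of barcodes comprising a cumulative
abundance percentile, diversity indices — Shannon
(−Σ pᵢ ln pᵢ), Simpson (1 − Σ pᵢ²), inverse Simpson (1/Σ pᵢ²), Gini
(Σᵢⱼ|xᵢ−xⱼ| / 2n²μ, zeros included) — and upper-tail hypergeometric
enrichment of clones across cell partitions with BH correction.

**Simulation.** A seeded generator emits FASTQ/FASTA/SAM/whitelist files
with known ground truth — IUPAC-patterned barcode libraries (e.g.
repeating `"WSN"`), log-normal clone abundances, staggers, substitution
errors with a two-point Phred model, cell barcodes and UMIs, PCR
duplication, planted chimeras and UMI errors — so every pipeline stage is
testable end to end.

## Worked example

Simulate a noisy bulk barcode-seq sample and quantify it against its own
library:

```r
library(barkit)

cfg <- sim_config(n_barcodes = 50, n_reads = 10000, sub_error_rate = 0.01,
                  seed = 1)
lib <- generate_library(cfg)
sim <- simulate_bulk(cfg, lib)

ec  <- extract_config(upconstant = cfg$upconstant,
                      downconstant = cfg$downconstant,
                      constants_mode = "both", barcode_length = 60)
res <- run_bulk_workflow(sim$reads, cfg = ec, reference = lib,
                         align_cfg = align_config(3))
unlist(res$qc$counters)
#>           input    quality_pass complexity_pass  constant_found
#>           10000           10000           10000            9909
#>     length_pass        assigned
#>            9908            9887

recovered <- setNames(numeric(50), names(sim$truth))
recovered[names(res$counts)] <- res$counts
cor(recovered, sim$truth)
#> [1] 0.9999638

head(sort(res$counts, decreasing = TRUE), 5)
#> BC_21 BC_46 BC_24  BC_9 BC_44
#>   812   784   735   733   665
```

At 1% per-base substitution error, ~1% of reads lose a constant region or
pick up enough barcode errors to go unassigned; the surviving counts
correlate with the simulated truth at r > 0.999. Downstream:

```r
ac <- annotated_counts(counts_from_tallies(list(S1 = res$counts)))
sample_diversity(ac, "shannon")   # 3.4109  (max ln 50 = 3.912 if uniform)
sample_diversity(ac, "gini")      # 0.5391  (log-normal skew, not uniform)
percentile_barcodes(ac$counts[, 1], 0.95)   # 37 barcodes hold 95% of reads
```

A shell interface wrapping the same functions ships in `inst/cli/barkit`
(subcommands `bulk`, `sc`, `spatial`, `analyse`, `simulate`), configured
by flags or a YAML file using the same parameter names.

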