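---
title: "Methods: barcode extraction, quantification and clonal analysis in barkit"
author: "barkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode extraction, quantification and clonal analysis in barkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barkit)
```

# Background

Cellular (lineage) barcoding marks individual clones with heritable
synthetic DNA tags that are read out by high-throughput sequencing, at the
population level (bulk barcode-seq), in single cells (expressed barcode
amplicons alongside scRNA-seq) and spatially (coordinate-tagged capture
spots). `barkit` implements the full path from raw reads to clonal
statistics: read-level QC and barcode extraction, reference-based or
reference-free quantification, single-cell UMI handling including
PCR-chimera removal, and downstream diversity and enrichment analysis. A
seeded simulator emits every input format with known ground truth, so each
stage can be validated end to end without external data.

# Read-level processing

## Pair merging

Overlapping mates are merged by scanning every candidate overlap from the
longest down to `merge_min_overlap` and scoring each by mismatch density
(mismatches divided by overlap length; an `N` never counts as a match).
The lowest density at or below `merge_max_mismatch_density` wins, with
ties broken toward the longer overlap. The consensus takes the
higher-quality base at each disagreement (read 1 on quality ties) and the
maximum of the two qualities — a deliberate simplification of
probabilistic quality recalibration that keeps merged qualities on the
original Phred scale.

## Quality and complexity filters

A read passes the quality filter when at least `pctqual` percent of its
bases reach Phred `minqual` (defaults 80% and Q20). The boundary is
inclusive: a 10-bp read with exactly 8 bases at Q20 passes at
`pctqual = 80`. Sequence complexity is the percentage of bases that
differ from their next base, so homopolymers score 0 and perfectly
alternating sequences 100; semi-random barcode designs built from
repeating IUPAC triplets such as `"WSN"` warrant thresholds around 65%.
The score is invariant under reversal and complementation, which the test
suite exercises as a property.

## Constant-region trimming

The variable barcode is located by finding the user-defined flanking
constant sequences. Matching is substitution-only: barcode constructs fix
the positions of their constant regions, and disallowing indels keeps
every candidate placement unambiguous and testable. Placements are either
full internal matches or partial anchors — the tail of the upstream
constant at the read start, or the head of the downstream constant at the
read end — covering at least `up_coverage`/`down_coverage` bases, which
accommodates staggers and reads that end inside a constant. A placement is
accepted when its mismatch fraction is at most `constant_error_rate`
(inclusive); among acceptable placements the winner has the fewest
mismatches, then the longest aligned length, then the leftmost (upstream)
or rightmost (downstream) position. These tie-breaks are arbitrary but
deterministic, chosen so that identical inputs always yield identical
outputs.

Five modes cover common construct designs: `up`, `down`, `both`,
`up_optional_down` and `any`. After trimming, the length policy rejects
barcodes shorter than `min_readlength`, longer than `barcode_length_max`,
or — when both flanks were found — different from an exact
`barcode_length`.

The helper `barcode_length_bounds()` exposes the construct-geometry
arithmetic used to choose length settings: for a 150-bp read with a 0–6-bp
stagger, 6-bp UMI, 22-bp primer region and a 15-bp downstream anchor, the
longest extractable barcode is 150 − 0 − 6 − 22 − 15 = 107 bp. The lower
bound is not derivable from geometry alone and is treated as a
user-supplied floor. `accepted_length_window()` computes the
nominal ± clustering-distance window used by tools that couple length
tolerance to the clustering radius (e.g. 92–108 bp for a 100-bp barcode at
distance 8).

# Quantification

## Reference-based assignment

When a reference library of known barcodes is available (obtained by deep
sequencing of the plasmid pool), extracted barcodes are assigned by
Hamming distance with at most `max_mismatches` (0–3). Shorter reads are
anchored: they are compared only against the length-matched prefix and
suffix of each entry, reflecting partial coverage of a fixed-length
barcode. Ties between two or more entries at the best distance are
discarded as ambiguous rather than assigned arbitrarily — discarding
avoids fabricating counts, and the ambiguous tally is reported in the QC
counters.

## Reference-free clustering

Without a reference, sequencing-error variants are merged by greedy sphere
clustering: sequences are visited in count-descending order (ties
lexicographic); each either founds a centroid or is absorbed by an
existing centroid within Levenshtein `distance` whose *original* tally is
at least `ratio` times its own (default distance 3, ratio 5). Using the
centroid's canonical count rather than its running sum makes the rule
order-independent of earlier absorptions and directly testable against a
brute-force oracle, which the suite does on hundreds of random instances.
This greedy rule is simpler than message-passing clustering used by some
tools; the two can differ on adversarial inputs, but the ratio semantics
are preserved and the greedy rule is exactly reproducible. Total count
mass is conserved by construction. In the reference-free path, barcodes
are first truncated to the shortest observed length unless both constant
regions were trimmed, in which case full-length variable barcodes are
retained.

# Single-cell and spatial processing

Read 1 carries the cell barcode and UMI per a `C…CN…N` pattern (default
16 + 10). Cell barcodes are filtered against a whitelist, optionally
rescuing barcodes at Hamming distance 1 from exactly one entry (off by
default, since unconditional correction can merge distinct cells). When
no whitelist exists, a simple knee rule calls cells: the threshold is one
tenth of the read count at the 99th percentile of the top
`expected_cells` barcodes. This intentionally plain rule is documented
and deterministic; externally derived whitelists are preferred when
available.

## PCR chimera removal

PCR chimeras arise when a partial amplicon primes a different template,
attaching a cell-barcode/UMI pair to the wrong lineage barcode. For every
(cell, UMI) group, only the lineage barcode with strictly maximal read
support survives; groups whose maximum is shared are removed entirely as
ambiguous. Chimera removal precedes UMI collapsing, since collapsing
first could merge the evidence needed to recognise a chimera.

## UMI collapsing

UMI sequencing errors inflate molecule counts. Within each (cell, lineage
barcode) combination, UMIs are deduplicated with the directional
adjacency network that is the established standard for UMI error
correction: visiting UMIs in read-count-descending order, a cluster
expands along directed edges from a member `a` to an unassigned UMI `b`
with `lev(a, b) ≤ d` and `count(a) ≥ 2·count(b) − 1`. Two error variants
of one molecule (up to `2d` apart) merge through their common parent,
while two genuine molecules of similar abundance remain separate — a
plain distance-sphere absorption cannot do both, which is why the
directional rule was chosen. At `d = 0` every distinct UMI counts.

## Per-cell filters and annotation

Ambient-RNA noise is suppressed by two per-cell filters: a minimum UMI
count per (cell, lineage barcode), then removal of barcodes below
`dominant_fraction` of the cell's top barcode (inclusive: a barcode
exactly at the fraction is kept). Cells with no surviving barcodes are
dropped but counted, keeping detection-rate denominators computable.
Annotations are comma-separated, UMI-count-ordered per-cell lists;
`dominant_barcode()` returns the top barcode per cell, with no call on
top-two ties. Spatial spots (identifiers encoding `x_y` coordinates) are
aggregated to square bins by floor division of the coordinates, summing
UMI counts; total mass is conserved for every bin size.

# Downstream clonal analysis

Counts from multiple samples are combined over the union barcode set with
zero fill and carried alongside sample metadata. The analysis layer
provides:

* **Depth filter** — removes samples whose total reads fall below a
  percentile of the per-sample totals. The percentile uses linear
  interpolation between order statistics (R's default type-7 convention);
  the convention is stated because the rule is otherwise underdetermined.
* **Count thresholds** — keep a barcode only if its count (absolute) or
  within-sample proportion (relative) reaches the threshold in at least
  `min_samples` samples, boundaries inclusive. Filters only remove rows or
  columns; surviving counts are never altered.
* **Replicate handling** — pairwise correlation within replicate groups
  over the full barcode universe (zeros included); groups whose minimum
  pairwise correlation exceeds the threshold (default 0.9) collapse to
  their element-wise arithmetic mean (a geometric option exists but is off
  by default, "averaged" being read literally). Constant columns have
  undefined correlation and are never collapsed silently.
* **Normalisation** — counts per million, percentage abundance, or TMM
  scaling (via the standard weighted trimmed-mean-of-M-values
  implementation) followed by CPM on effective library sizes.
* **Diversity** — Shannon (natural log), Simpson in complement form
  (1 − Σp²), inverse Simpson, and the Gini index computed from the
  mean absolute difference over the *full* barcode universe including
  zeros, measuring inequality of the clone-size distribution within a
  sample. The Simpson convention and the zero-inclusive Gini are stated
  choices; both conventions exist in the literature.
* **Enrichment** — upper-tail hypergeometric tests of a cell group
  (e.g. a clone) across partitions (e.g. transcriptional clusters), with
  Benjamini–Hochberg adjustment across partitions and −log10 p reported
  for plotting.

# The simulator and what passing tests show

`sim_config()` defaults describe the emulated study conditions: a 50-entry
library drawn from 20 repeats of the IUPAC triplet `"WSN"` (60 bp),
constant flanks `CGATTGACTA`/`TGCTAATGCG`, a 0–6-bp stagger, 100-bp reads,
log-normal(0, 1) clone abundances, 10,000 bulk reads, and a two-point
Phred model (Q37 at correct bases, Q14 at substituted ones). Single-cell
runs default to 100 cells, one lineage barcode per cell, Poisson(10)+1
molecules per (cell, barcode) and Poisson(2)+2 reads per molecule — the
+2 floor reflects PCR duplication and guarantees that a chimera can always
be planted at strictly lower support. Chimeras reuse an existing
(cell, UMI) with a different lineage barcode; a tie-planting mode
exercises ambiguous-tie removal. UMI errors substitute one UMI base per
read at the configured rate. All randomness is fixed by the seed, and
identical configurations produce byte-identical files.

The simulator is deliberately idealised: substitution-only errors (no
indels, matching the substitution-only matcher), independent errors with a
two-point quality model rather than learned per-cycle profiles, no ambient
RNA, no barcode-swapping between samples, and no amplification bias beyond
the reads-per-UMI distribution. Passing its recovery tests therefore
demonstrates the correctness of the implemented rules under their own
assumptions — exact recovery at zero noise, Pearson ≥ 0.99 at 1%
substitution error, complete removal of lower-support chimeras, ≥ 99%
exact molecule counts at 5% UMI error — not robustness to every artefact
of real libraries. Problem sizes in the shipped tests (10,000 bulk reads
over 50 clones; 100 cells; 200 random clustering instances of up to 50
sequences) were chosen as the smallest sizes at which the statistical
properties are stable.

# Numerical and degenerate-input choices

Phred encoding is fixed at +33. `N` bases always count as mismatches in
merging, constant matching and reference assignment. Empty FASTQ files
yield empty streams; truncated records are hard errors naming the record
index. Duplicate barcode rows in a counts file are summed with a warning
(tolerating pre-aggregated partial files), while duplicate reference
names or sequences are hard errors, since an ambiguous reference
invalidates assignment. Zero-total samples are hard errors at
normalisation time, named by sample. QC counters are validated to be
non-increasing along the pipeline order before a report is written; a
violation is a bug, not a data property, and raises an error.

# Known limitations

Constant-region matching does not model indels, so reads with an indel
inside a constant region are lost rather than rescued. Reference
assignment is a linear scan, adequate for desk-scale libraries (10^2–10^4
barcodes) but not indexed for very large references. The knee-calling rule
is intentionally simple and should be replaced by an external whitelist
when droplet-level accuracy matters. Evolving (CRISPR-edited) barcodes,
interleaved FASTQ, CRAM and 10x molecule-info files are out of scope.
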