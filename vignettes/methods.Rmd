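---
title: "Methods: tile-based ChIP enrichment, piRNA quantification, and chromodomain comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinotools)
```

# Scope and model

rhinotools quantifies where the germline HP1-family protein Rhino binds
chromatin and which piRNA populations depend on it. The package covers
five computations: curation of fixed-width genomic tiles, ChIP-seq
enrichment on tiles and on transposon consensus sequences, small-RNA
processing and piRNA counting with a dependence classifier, scanning of
labeled HP1-family alignments for subfamily-discriminative residues, and
rigid-body comparison of chromodomain structures. Read alignment itself is
out of scope: alignments are consumed as SAM/BAM (or equivalent tables),
with hit multiplicity taken from an `NH` tag when present and otherwise
derived by grouping records by read name, which reproduces an
all-best-stratum aligner report.

All genomic intervals are 0-based and half-open internally; BED is read
and written natively and coordinates are converted at the boundary.
Enrichment is computed and stored in linear space; log2 is applied only at
reporting, so the background correction stays multiplicative.

# Tile curation

`make_tiles()` partitions each chromosome into consecutive windows of
`tile_size` bases (default 1000). A short terminal tile is retained and
its true length is used in every per-base computation; dropping
chromosome ends silently would bias coverage summaries, and the
mappability and input-deviation filters already remove pathological short
tiles.

`curate_tiles()` applies three independent filters, each recorded in
`excluded_by` so a tile can carry several labels:

* **mappability** — excluded when the fraction of the tile covered by
  blocks of continuous mappability is below `mappability_min`
  (default 0.25);
* **input_deviation** — excluded when the representative input count
  deviates more than `input_deviation_fold` (default 3) from the
  across-tile median. The deviation is read as directionless, so the
  filter is two-sided (`count > 3·median` or `count < median/3`) with
  strict inequality: a count of exactly three times the median is kept.
  The high side removes collapsed-repeat pileups, the low side dead
  zones;
* **ko_residual** — when knockout ChIP enrichments are supplied, tiles
  with log2 enrichment above `ko_residual_log2_max` (default 1.0) are
  flagged. What counts as "strong residual signal" is a genuinely open
  choice; a configurable log2 threshold is the simplest testable rule.

Curation is idempotent and monotone in the mappability threshold; both
properties are asserted in the test suite.

# ChIP enrichment

Per tile, only genome-unique reads (`n_best_hits == 1`) are counted, and
each read is assigned to exactly one tile by its midpoint. The assignment
rule is not dictated by the data model — 5′-end assignment is available
via an option — but the midpoint guarantees that a read spanning a tile
boundary is counted once, on the side containing most of it.

Raw enrichment of tile *t* is

$$E(t) = \frac{c_t \cdot s / C + p}{i_t \cdot s / I + p}$$

with counts *c*, *i*, library depths *C*, *I*, depth scale *s* (default
10⁶) and pseudocount *p* (default 1). The pseudocount bounds ratios at
empty tiles (0/0 → 1) and is negligible wherever coverage is appreciable
at the per-million scale.

`background_correction()` multiplies all enrichments by
`1 / median(E over background units)`, pinning the median background
enrichment at exactly 1. This removes differences in ChIP efficiency
between samples. The background unit set defaults to all curated tiles —
the genome is overwhelmingly non-enriched, so the genome-wide median is a
robust background estimate — and can be restricted to an explicit tile
set. Replicates are averaged as the arithmetic mean of per-unit log2
enrichments.

On transposon consensus sequences, reads longer than 23 nt
(`te_min_read_length = 24`) are kept, multimappers are resolved by
`assign_multimappers()` — the unique minimal-mismatch hit wins, ties are
broken uniformly at random — and per element the depth-normalized
coverage is averaged over all consensus positions before the same
pseudocount ratio and the tile-derived correction factor are applied.
Random tie-breaking uses one seeded generator per library with reads
processed in lexicographic read-id order, so the assignment is
bit-reproducible regardless of input record order.

# Small-RNA processing and piRNA counting

Raw reads follow the cloning architecture: 4 random nt, insert, 6 random
nt, a 5 nt barcode, then the constant 3′ linker. `trim_reads()` locates
the leftmost linker occurrence allowing `max_linker_mismatches`
(default 1), strips linker, barcode and random bases, and rejects reads
with no linker (`no_adapter`) or an insert shorter than `min_insert`
(default 18 nt, `too_short`). The component sizes are fixed by the
chemistry but their order is configurable through `adapter_scheme()`.
Barcodes and the random nucleotides are recorded but reads are not
collapsed by them: whether duplicates should be removed is left to the
caller, and the default preserves raw counts.

Categorization is annotation-driven: a read is `filtered_ncrna` if any
genome hit overlaps an rRNA/tRNA/snRNA/snoRNA locus or the mitochondrial
chromosome, else `mirna` if any hit overlaps a miRNA locus (miRNA
identity is locus-defined, not length-defined, because the normalization
target is *sequenced microRNA reads*), else `pirna_candidate` if the
insert length falls in `pirna_length_range` (default 23–29 nt), else
`other`. Every read lands in exactly one category; the run report proves
conservation.

All downstream tables are scaled by the same factor
`mirna_norm_target / miRNA reads` (default 10⁶ target). Per transposon,
only antisense-assigned piRNAs are counted and the count is normalized to
element length (per kilobase). Per cluster, a read counts once iff the 5′
end of **every** one of its genome hits lies within that single cluster
— the 5′ end being the leftmost base on the plus strand and the
rightmost on the minus strand. Per-tile counts inside clusters reuse the
same locus-unique rule, assigning each qualifying read to the tile of its
leftmost hit; tiles with a zero count in any analyzed genotype are
excluded from fold-change reporting rather than patched with
pseudocounts.

`classify_dependence()` calls an element *dependent* when its normalized
antisense count in the test condition is at most `control /
dependence_fold` (default 2). The boundary is inclusive — an exactly
twofold reduction is dependent — because "a twofold reduction" is read as
"at least twofold" and a fixed rule is required for testability. Elements
with a zero control count are reported `unclassifiable` instead of
producing infinite ratios.

# Subfamily residue scanning

`condense_alignment()` removes columns whose non-gap fraction is below
`msa_min_column_coverage` (default 0.70, threshold inclusive) and returns
a column index map. `column_discrimination()` scores each remaining
column by frequency contrast: the focal consensus is the modal non-gap
residue among focal rows (ties broken alphabetically), and
`score = focal_freq − other_freq` with gaps counting in both
denominators, which penalizes sparse columns rather than letting them
score spuriously high. A score of 1 means the consensus residue occurs
in every focal row and in no other row — the pattern of the
aspartate-to-glycine change that separates Rhino from the other HP1
proteins.

This deterministic score stands in for sampling-based feature-weighting
methods (Multi-RELIEF style) whose internal parameters are not
reproducible here. The two approaches agree on clear-cut columns (score
1), which are the biologically reported ones; ranking near the threshold
may differ, and the score should be treated as a screen, not a test
statistic. `find_subfamily_indels()` reports columns occupied almost
exclusively by the focal subfamily (insertion; defaults: ≥90% focal
occupancy, ≤10% other occupancy) or the reverse (deletion). Note that a
focal-only insertion column is itself perfectly discriminative, so
substitution ranking should exclude indel-flagged columns, as the test
suite does.

# Structure comparison

`superpose()` implements the closed-form least-squares rigid
superposition (Kabsch, via SVD) over paired atom lists — by default Cα
atoms of caller-supplied residue ranges, paired by order. Pairing by
selection order rather than by sequence alignment is deliberate: the
published comparisons name structurally equivalent ranges explicitly
(e.g. chromodomain residues 26–57), and embedding an aligner would hide
that choice. A proper rotation (det = +1) is enforced through the sign
correction of the SVD; selections with fewer than three atoms or with
collinear geometry (second singular value below 10⁻⁸ of the first) are
errors because the rotation is not determined.

`detect_clashes()` lists inter-group atom pairs closer than the sum of
van der Waals radii (C 1.70, N 1.55, O 1.52, S 1.80 Å) minus
`clash_tolerance` (default 0.4 Å), sorted by overlap depth. Hydrogens
are excluded by default since crystal and predicted structures carry them
inconsistently. Alternate locations are resolved to the highest
occupancy at load time, waters dropped, and only the first model of a
multi-model file is used.

# Synthetic data: what it emulates, and what it does not

The generators produce the statistical structure the pipelines consume,
with recorded ground truth:

* `sim_genome()` — by default two 100-kb chromosomes, two 10-kb piRNA
  clusters, three 2-kb transposon consensi each embedded twice with the
  copies of every element spread across *different* clusters (so
  transposon reads are legitimate multimappers but never locus-unique),
  miRNA and structural ncRNA loci, a 5-kb mitochondrial chromosome, and
  two planted 3-kb low-mappability blocks whose complement forms the
  mappability track.
* `sim_chip()` — input midpoints uniform over mappable space; ChIP reads
  sampled per tile proportional to multiplier × mappable length, with
  background 1 and planted domains at 2×, 4× and 8× (five tiles each).
  At the default 10⁵ reads per library each tile receives ≈500 input
  reads, giving a relative standard error of the per-tile ratio of ≈5%,
  which motivates the 15% recovery band used in testing.
* `sim_srna()` — inserts wrapped in the full adapter architecture;
  transposon piRNAs drawn from the consensus with genome hits at every
  embedded copy; locus-unique reads from non-repetitive cluster
  sequence; planted miRNA and ncRNA reads. Expected category counts,
  normalization factors and normalized count tables are computed
  analytically, so recovery of these quantities is exact, not
  statistical.
* `sim_msa()` — a shared-consensus family with one planted fully
  discriminative column, one planted focal-only insertion and several
  low-coverage columns.

Every generator is a pure function of its arguments and an integer seed.
Reads are emitted pre-aligned (SAM-compatible hit tables with correct
multiplicity) for ChIP, and raw FASTQ plus a companion exact-match
alignment table for small RNA, keeping the tests hermetic.

What the simulations do **not** model: sequencing errors and quality
variation, PCR duplication, mismatch-containing alignments (all planted
hits are exact), copy-number divergence between genomic transposon
insertions and their consensus, chromatin-accessibility bias in input
libraries, and genuinely ambiguous cluster boundaries. Passing recovery
tests therefore demonstrates correctness of the counting and
normalization logic under the stated sampling model, not robustness to
every artifact of real libraries.

Problem sizes in the routine test-suite runs are deliberately modest
(10⁵-read ChIP libraries, small-RNA libraries of a few thousand reads,
one hundred randomized instances for the locus-unique counting oracle);
they are chosen so the binomial tolerances above are meaningful while the
whole suite stays fast.

# Numerical and degenerate-input conventions

* Background correction divides by the median of the background set;
  a zero median is an error, and after correction the background median
  equals 1 to floating-point identity (`x/x` per unit).
* Zero library depth, zero-length elements and empty background sets are
  hard errors; empty alignment tables flow through counting functions as
  all-zero results.
* A library with zero miRNA reads is a hard error everywhere a
  normalization factor is needed.
* Consensus ties in the alignment scan break alphabetically; multimapper
  ties break by one seeded draw per read in lexicographic read-id order.
* The exactly-twofold dependence boundary is dependent; the
  exactly-70%-coverage column is kept; the exactly-threefold input
  deviation is kept.

# Known limitations

* The residue scan is a deterministic surrogate for sampling-based
  subfamily weighting; near-threshold rankings are method-dependent.
* The knockout-residual tile filter depends on a configurable log2
  cutoff with no canonical value.
* Superposition pairs atoms by order within the stated ranges; it does
  not check residue identity, so the caller owns the structural
  equivalence of the two selections. The published chromodomain
  comparison (HP1a from PDB 6MHA onto Rhino residues 26–57 of PDB 4U68,
  RMSD 0.55 Å) can be reproduced with `superpose()` once the two RCSB
  coordinate files are available locally; they are not redistributed
  with the package.
* Cluster definitions, mappability tracks and annotations are inputs;
  the package does not construct them.
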