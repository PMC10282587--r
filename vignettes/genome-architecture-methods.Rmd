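---
title: "Methods: genome architecture and biomineralization screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome architecture and biomineralization screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glassarch)
```

This vignette documents the models, conventions and design choices
behind each analysis stage, and what the synthetic-data generators do
and do not emulate.

## Coordinate model

All internal coordinates are 0-based half-open, converted once at the
GFF3 boundary (`read_gff()` / `write_gff()` handle the 1-based inclusive
convention). This makes interval arithmetic (`length = end - start`,
adjacency, containment) safe without the off-by-one case analysis that
1-based closed coordinates force. A gene's span is the envelope over all
its transcripts; per-gene exonic bp is the length of the union of its
exon intervals, so overlapping isoform exons are never double-counted.

## Nested genes

Gene *G* is nested in host *H* when both lie on one scaffold and *G*'s
span fits entirely inside a *single* intron of at least one transcript
of *H*. Three deliberate choices:

* **Strand-agnostic by default.** Nesting is a positional property;
  compact genomes nest genes on both strands. A
  `require_opposite_strand` flag restricts to antisense hosts for users
  who want the conservative reading.
* **Single-intron containment.** A gene whose span crosses a host exon
  overlaps host exonic sequence and is not nested, even if it is inside
  the host's overall span.
* **Each nested gene counted once**, however many hosts or isoforms
  contain it; all (nested, host, transcript, intron) pairs are listed
  exhaustively in the report.

The detector is interval containment via `GenomicRanges::findOverlaps`
with `type = "within"`; the test suite holds it equal to a brute-force
all-pairs containment scan on hundreds of random annotations whose genes
overlap freely.

## Microsynteny

The hit table is the 12-column BLAST/DIAMOND tabular format.
High-copy-family removal drops every protein participating in more than
`max_hits = 50` retained hits, together with all its hits, iterated to a
fixed point — removal can drop other proteins below threshold, and the
fixed point makes the rule order-independent. This removal semantics
(both sides, iterative) is one reading of a per-protein hit cutoff; it
is configurable because other tools apply per-query caps instead.

Anchors are best-hit-per-query ("unidirectional"): highest bitscore,
ties by smaller evalue, then lexicographic subject id, for determinism.
Reciprocal-best filtering can be layered on by the caller but is not the
default.

Chaining is greedy left-to-right within each scaffold pair: anchors
sorted by a-side ordinal extend the open chain when at most `max_gap`
genes are skipped on either side and the b-side ordinal continues the
chain's direction; the second anchor fixes the direction; chains of
`min_block = 3` or more anchors become blocks. Greedy chaining is simple
and deterministic, and with the default `max_gap = 5` tolerates the
single-gene insertions and interleaved tandem duplicates that real
scaffold pairs show, at a known cost: a short inverted segment
(length ≤ `max_gap + 1`) adjacent to a collinear run can have its first
anchor absorbed by the preceding chain. Block counts are therefore
parameter-sensitive, and analyses that need exact planted-structure
recovery (as in the tests) use `max_gap = 0`.

Scaffold-pair significance uses the 2×2 table (pair hits; a-side
elsewhere; to-b-side from elsewhere; rest) with a one-sided (greater)
Fisher's exact test — enrichment is the only meaningful direction — and
Benjamini–Hochberg adjustment across tested pairs. Pairs with zero hits
are not tested, so vacuous p = 1 rows do not inflate the BH denominator.

## Trans-spliced leader detection

A spliced leader cannot align as a genomic exon, so full-length cDNA
reads show it as a soft clip (`S`) at the transcript 5′ end: a leading
`S` for plus-strand alignments, a trailing `S` for minus-strand ones
(whose stored sequence SAM keeps in reference orientation, hence the
reverse-complement on extraction). Hard clips carry no sequence and
never yield candidates. Secondary and supplementary alignments are
excluded so each read contributes once.

The default search window of 20–60 bp brackets leader-scale clips while
excluding adapter-scale and exon-scale artefacts; the histogram peak is
the windowed mode with ties broken toward the smaller length. Consensus
building aligns clips at their 3′ (alignment-adjacent) ends because a
fixed leader presents with a ragged 5′ end when molecules are degraded;
the per-position majority over the peak-length window, with alphabetical
tie-break, gives a deterministic consensus. With per-base error
*e* ≤ 0.1 and hundreds of leader reads, the majority base is correct per
position with overwhelming probability, which the simulation tests
exercise at *e* = 0.05.

## Compositional-bias screen

Per-protein residue frequencies are computed over the 20 standard amino
acids only; ambiguous letters are excluded from numerator and
denominator, and a trailing stop is stripped. The reference table is the
per-residue empirical 99th percentile (nearest-rank, i.e. inverse ECDF)
of these frequencies over reference proteins with ≥ 50 counted residues.
Nearest-rank was chosen over interpolated percentiles for determinism
and because the screen's semantics ("top 1%") are about ranks, not
interpolated values. The same 50-residue floor gates the screen itself:
very short proteins have degenerate compositions that would otherwise
dominate the flags. Any reference proteome FASTA is accepted; SwissProt
is the natural choice for a real screen.

Candidate narrowing keeps proteins whose biased residues intersect
DEHPST — the residue classes recurring in biomineralization scaffold
proteins — with adjusted p ≤ 1e-4 and the required fold-change
direction. The bias residue itself must be in the allowed set; an
alternative reading (any bias plus separate DEHPST enrichment) was
rejected as weaker.

Cleavage scanning matches `[VL]GG` with the cut between the glycines,
reporting overlapping matches; fragment masses are Expasy average
residue masses plus one water (18.0153 Da), the right scale for
comparison with SDS-PAGE band estimates (monoisotopic masses would be
systematically low by ~0.06%).

## Assembly ranking and contiguity

Metrics are ranked per column (1 = best in the metric's direction),
ties receive average ranks to avoid input-order dependence, and the
weighted rank sum orders assemblies (ties broken by id). Ranks make the
aggregation invariant to monotone rescaling of any metric. The shipped
default scheme carries the seven standard metrics at unit weight;
real evaluations supply their own weights. N50 uses the
cumulative-≥-half convention with ties toward the larger scaffold, and
N50/total-length is reported because it is comparable across genome
sizes (chromosome-scale assemblies of typical karyotypes sit near 0.02
or above). The contaminant screen flags scaffolds with GC above 0.40
and RNA coverage below 1× — poly-A selected eukaryotic libraries leave
bacterial scaffolds essentially uncovered.

## Synthetic data: what it emulates, and what it does not

The generators are seeded (outputs byte-identical per seed; the caller's
RNG state is restored) and each returns the planted truth alongside the
data.

* `simulate_annotated_genome()`: densely packed genes, log-normal
  introns (median ≈ 300 bp, between the short-intron regimes of compact
  sponge genomes), a tunable single-exon fraction, and planted nested
  genes that are single-exon and strictly interior to one host intron
  with ≥ 10 bp margins — recovery is exact by construction, separating
  detector correctness from definitional edge cases. Contaminant
  scaffolds get GC 0.55 and zero coverage.
* `simulate_ortholog_pair()`: species B's gene order is A's transformed
  by disjoint within-scaffold inversions, lineage-specific insertions,
  and an optional interleaved tandem array; the hit table carries the
  true ortholog map at top bitscore plus paralog and spurious decoys at
  lower bitscore, so best-hit reduction recovers the planted map
  exactly.
* `simulate_leader_reads()`: full-length cDNA alignments in text SAM
  with the leader soft-clipped in full and uniform substitution errors
  across the read. No indels, homopolymer artefacts, partial leader
  mapping or chimeras — so passing tests show orientation handling and
  consensus statistics are correct, not that the method is robust to
  every basecaller pathology (a `ragged` truncation knob is the obvious
  extension).
* `simulate_proteome()`: background and reference drawn from one
  realistic residue-frequency vector; planted proteins are constructed
  to exceed the reference P99 for one DEHPST residue by a margin, so
  recall must be 100% and false flags match the ~1%-per-residue
  self-screen calibration. Expression padj values are drawn directly
  (uniform nulls, near-zero planted) because the DE model itself is out
  of scope.
* `simulate_assembly_metrics()`: random metric tables, optionally with
  one assembly made strictly best everywhere.

Real data differ in ways the simulators deliberately ignore: overlapping
and nested-in-nested gene chains beyond one level, alternative isoforms
per gene (the simulators emit one transcript per gene; the analysis code
handles many), sequencing indels, and correlated residue composition
within protein families. Test results therefore validate the
algorithms' contracts, not field performance on any particular dataset.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make
the statistical assertions sharp while staying quick on a laptop:
2000-gene genomes for nested recovery, 150–200-gene ortholog pairs,
5000 reads for leader statistics, a 10 000-protein reference for
percentile calibration, exhaustive Fisher verification over all 2×2
tables with N ≤ 40 plus 5000 random tables with N ≤ 200 (at 1e-12
agreement with an independent hypergeometric enumeration), and 1000
random proteins for cleavage mass conservation.
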