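# glassarch

Genome-architecture and biomineralization-candidate analyses for compact
animal genomes, motivated by glass sponge (Hexactinellida) genomics.

Glass sponge genomes are small (tens of Mb), gene-dense, and unusual in
several ways that standard annotation summaries miss: a large fraction of
genes sit entirely inside the introns of other genes ("nested genes"),
local gene order is strongly conserved between species (microsynteny),
mRNAs carry a short trans-spliced leader that surfaces as soft-clipped
read prefixes in long-read alignments, and candidate biomineralization
proteins are recognizable not by homology but by extreme amino-acid
compositional bias. `glassarch` implements each of these analyses as a
tested, reusable R function, together with seeded simulators that
generate inputs with known ground truth so the whole pipeline can be
validated without any external data.

## What it computes

* **Nested genes** — gene *G* is nested in host *H* when *G*'s span lies
  entirely within a single intron of at least one transcript of *H*
  (same scaffold, strand-agnostic by default). Reports counts, the
  nested fraction of genes, and the nested fraction of exonic bp.
* **Microsynteny** — from a 12-column protein hit table: iterative
  removal of proteins with more than 50 hits (high-copy families),
  best-hit-per-query anchors, greedy collinear chaining into blocks of
  ≥ 3 anchors with a configurable gap tolerance, and a one-sided
  Fisher's exact test per scaffold pair on the 2×2 table
  (*a* = hits between the pair, *b* = a-side hits elsewhere, *c* =
  b-side hits from elsewhere, *d* = the rest), BH-adjusted.
* **Trans-spliced leader** — strand-aware extraction of 5′ soft clips
  (`S` in the CIGAR) from text SAM, a clip-length histogram with
  windowed modal peak, and a 3′-anchored majority consensus with
  leader-bearing read fraction and top-leader share.
* **Compositional bias** — per-protein amino-acid frequencies screened
  against the per-residue 99th percentile (nearest-rank) of a reference
  proteome; candidates narrowed to DEHPST-type bias with significant
  upregulation (padj ≤ 1e-4), plus `[V/L]G′G` cleavage-motif scanning
  and average-mass prediction of the fragments.
* **Assembly selection** — weighted rank aggregation over the seven
  standard evaluation metrics (N50, size delta, mean scaffold length,
  scaffold count, BUSCO single-copy complete, RNA/DNA mapping rates),
  each with its own optimization direction; plus N50/total-length
  contiguity statistics and a GC × RNA-coverage contaminant screen.

## Worked example

```r
library(glassarch)

# a simulated compact genome: 1000 genes, 12% planted nested
sim <- simulate_annotated_genome(7, n_genes = 1000, nested_fraction = 0.12)
detect_nested_genes(sim$ann)
#> nested_report: 120 nested of 1000 genes (12.0%); 7.6% of exonic bp

# microsynteny across a simulated ortholog pair with one inversion
ortho <- simulate_ortholog_pair(7, n_genes = 150, inversions = list(c(40, 49)))
oa <- build_gene_order(ortho$ann_a); ob <- build_gene_order(ortho$ann_b)
detect_synteny_blocks(best_hit_per_query(ortho$hits), oa, ob, max_gap = 0)
#> synteny_blocks: 4 blocks, 150 anchors
#>   block_id scaffold_a scaffold_b orientation size
#> 1        1       sa01       sb01           +   39
#> 2        2       sa01       sb01           -   10
#> 3        3       sa01       sb01           +   26
#> 4        4       sa02       sb02           +   75

# trans-spliced leader from 5000 noisy long reads, 4% leader-bearing
sl <- simulate_leader_reads(7, n_reads = 5000, leader_fraction = 0.04,
                            error_rate = 0.05)
reads <- read_sam(sl$sam)
ev <- extract_clips(reads, 20, 60)
h  <- clip_histogram(ev, c(20, 60))
leader_consensus(ev, h$peak_length, tolerance = 3, total_mapped = nrow(reads))
#> leader_motif: CTAAAGTCATAAGATATACTGACCCAGTCTGAAATCT
#>    213 leader reads; 4.3% of mapped reads; top exact leader 16.4%
```

The 10-gene inverted segment comes back as the single `-` block (size 10:
the planted genes 40–49), the leader consensus is the planted 37-mer
recovered exactly despite 5% per-base error, and the leader-bearing
fraction estimate (4.3%) sits within binomial sampling error of the
simulated 4%.

A thin command-line front end over the same functions is installed at
`inst/exec/glassarch.R` (`nested`, `stats`, `contiguity`, `screen`,
`synteny`, `transsplice`, `compbias`, `cleave`, `rank` subcommands).

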