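#' Detect genes nested inside introns of other genes
#'
#' A gene G is nested in a host H when both lie on the same scaffold and
#' G's full span (envelope over all its transcripts) falls entirely within
#' a single intron of at least one transcript of H. Strand is ignored by
#' default: compact genomes carry nested genes on both strands, and the
#' definition is purely positional. Genes overlapping host exons (i.e.
#' spanning more than one host intron) are not nested.
#'
#' @param ann An [annotation_set()].
#' @param require_opposite_strand If `TRUE`, only count hosts on the
#'   opposite strand of the nested gene.
#' @return Object of class `nested_report`: list with `pairs` (data.frame
#'   `nested_gene`, `host_gene`, `host_tx`, `intron_start`, `intron_end`),
#'   `nested_genes` (unique ids), `nested_gene_count`, `gene_count`,
#'   `nested_fraction`, and `nested_exonic_fraction` (exonic bp of nested
#'   genes over total exonic bp, exon unions per gene).
#' @export
detect_nested_genes <- function(ann, require_opposite_strand = FALSE) {
  stopifnot(inherits(ann, "annotation_set"))
  genes <- ann$genes
  introns <- ann_introns(ann)
  empty <- data.frame(nested_gene = character(), host_gene = character(),
                      host_tx = character(), intron_start = numeric(),
                      intron_end = numeric())
  pairs <- empty
  if (nrow(genes) && nrow(introns)) {
    gene_gr <- GenomicRanges::GRanges(
      genes$scaffold, IRanges::IRanges(genes$start + 1, genes$end))
    intron_gr <- GenomicRanges::GRanges(
      introns$scaffold, IRanges::IRanges(introns$start + 1, introns$end))
    ov <- GenomicRanges::findOverlaps(gene_gr, intron_gr, type = "within")
    gi <- S4Vectors::queryHits(ov); ii <- S4Vectors::subjectHits(ov)
    keep <- genes$gene_id[gi] != introns$gene_id[ii]
    if (require_opposite_strand) {
      g_strand <- .gene_strand(ann)[genes$gene_id[gi]]
      h_strand <- introns$strand[ii]
      keep <- keep & g_strand != h_strand & g_strand %in% c("+", "-") &
        h_strand %in% c("+", "-")
    }
    gi <- gi[keep]; ii <- ii[keep]
    if (length(gi)) {
      pairs <- data.frame(nested_gene = genes$gene_id[gi],
                          host_gene = introns$gene_id[ii],
                          host_tx = introns$tx_id[ii],
                          intron_start = introns$start[ii],
                          intron_end = introns$end[ii])
      pairs <- pairs[order(pairs$nested_gene, pairs$host_gene,
                           pairs$host_tx, pairs$intron_start), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  nested_ids <- sort(unique(pairs$nested_gene))
  exonic <- .gene_exonic_bp(ann)
  total_exonic <- sum(exonic)
  structure(list(
    pairs = pairs,
    nested_genes = nested_ids,
    nested_gene_count = length(nested_ids),
    gene_count = nrow(genes),
    nested_fraction = if (nrow(genes)) length(nested_ids) / nrow(genes) else 0,
    nested_exonic_fraction =
      if (total_exonic > 0) sum(exonic[nested_ids]) / total_exonic else 0),
    class = "nested_report")
}

#' @export
print.nested_report <- function(x, ...) {
  cat("nested_report:", x$nested_gene_count, "nested of", x$gene_count,
      sprintf("genes (%.1f%%); %.1f%% of exonic bp\n",
              100 * x$nested_fraction, 100 * x$nested_exonic_fraction))
  invisible(x)
}

# per-gene exonic bp as the union of exon intervals over all transcripts
.gene_exonic_bp <- function(ann) {
  ex <- ann$exons
  if (!nrow(ex)) return(stats::setNames(numeric(0), character(0)))
  gr <- GenomicRanges::GRanges(ex$gene_id,
                               IRanges::IRanges(ex$start + 1, ex$end))
  red <- GenomicRanges::reduce(gr)
  w <- tapply(GenomicRanges::width(red),
              as.character(GenomicRanges::seqnames(red)), sum)
  out <- stats::setNames(rep(0, nrow(ann$genes)), ann$genes$gene_id)
  out[names(w)] <- as.numeric(w)
  out
}

.gene_strand <- function(ann) {
  tx <- ann$transcripts
  stats::setNames(tx$strand[!duplicated(tx$gene_id)],
                  tx$gene_id[!duplicated(tx$gene_id)])
}

#' Bulk annotation statistics
#'
#' @param ann An [annotation_set()].
#' @return Object of class `genome_stats`: gene/transcript counts,
#'   single-exon transcript count, mean gene span length, mean transcript
#'   length (summed exon lengths), total exonic bp (exon unions per gene),
#'   intron count and mean intron length over all transcript introns.
#'   Means are `NA` when the denominator is zero.
#' @export
genome_bulk_stats <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  introns <- ann_introns(ann)
  structure(list(
    gene_count = nrow(ann$genes),
    transcript_count = nrow(ann$transcripts),
    single_exon_transcript_count = sum(ann$transcripts$n_exons == 1L),
    mean_gene_length = if (nrow(ann$genes))
      mean(ann$genes$end - ann$genes$start) else NA_real_,
    mean_transcript_length = if (nrow(ann$transcripts))
      mean(ann$transcripts$exonic_bp) else NA_real_,
    total_exonic_bp = sum(.gene_exonic_bp(ann)),
    intron_count = nrow(introns),
    mean_intron_length = if (nrow(introns))
      mean(introns$end - introns$start) else NA_real_),
    class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat("genome_stats:\n")
  for (n in names(x)) cat(sprintf("  %-30s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' Unique-intron profile of one scaffold
#'
#' Introns shared between isoforms are deduplicated by exact (start, end);
#' lengths are reported sorted longest-first for profile plots.
#'
#' @param ann An [annotation_set()].
#' @param scaffold Scaffold identifier present in the annotation.
#' @return Object of class `intron_profile`: `scaffold`, `introns`
#'   (data.frame `start`, `end`), `count`, `mean_length`, `total_length`,
#'   `lengths_sorted_desc`.
#' @export
scaffold_intron_profile <- function(ann, scaffold) {
  stopifnot(inherits(ann, "annotation_set"))
  if (!scaffold %in% ann$genes$scaffold)
    stop("unknown scaffold: ", scaffold)
  introns <- ann_introns(ann)
  introns <- introns[introns$scaffold == scaffold, , drop = FALSE]
  uniq <- unique(introns[c("start", "end")])
  uniq <- uniq[order(uniq$start, uniq$end), , drop = FALSE]
  rownames(uniq) <- NULL
  lens <- uniq$end - uniq$start
  structure(list(scaffold = scaffold, introns = uniq,
                 count = nrow(uniq),
                 mean_length = if (nrow(uniq)) mean(lens) else NA_real_,
                 total_length = sum(lens),
                 lengths_sorted_desc = sort(lens, decreasing = TRUE)),
            class = "intron_profile")
}

#' @export
print.intron_profile <- function(x, ...) {
  cat("intron_profile:", x$scaffold, "-", x$count, "unique introns, mean",
      round(x$mean_length, 1), "bp, total", x$total_length, "bp\n")
  invisible(x)
}

#' Assembly contiguity statistics
#'
#' N50 is the length of the scaffold at which the descending cumulative
#' length first reaches half the assembly (ties toward the larger
#' scaffold). The N50/total ratio indicates how close the assembly is to
#' chromosome scale (around 0.02 and higher for 10-30 chromosomes).
#'
#' @param seqs A [sequence_set()] or a numeric vector of scaffold lengths.
#' @param threshold Length threshold (bp) for the large-scaffold count.
#' @return Object of class `contiguity_stats`: `total_length`,
#'   `scaffold_count`, `n50`, `n50_over_total`, `scaffolds_over_threshold`,
#'   `fraction_over_threshold` (fraction of total length in scaffolds of
#'   at least `threshold` bp), `threshold`.
#' @export
assembly_contiguity <- function(seqs, threshold = 5e5) {
  lens <- if (is.numeric(seqs)) as.numeric(seqs) else nchar(as.character(seqs))
  if (!length(lens)) stop("no sequences")
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1]]
  over <- lens >= threshold
  structure(list(total_length = total, scaffold_count = length(lens),
                 n50 = n50, n50_over_total = n50 / total,
                 scaffolds_over_threshold = sum(over),
                 fraction_over_threshold = sum(lens[over]) / total,
                 threshold = threshold),
            class = "contiguity_stats")
}

#' @export
print.contiguity_stats <- function(x, ...) {
  cat(sprintf(paste0("contiguity_stats: %d scaffolds, %.0f bp, N50 %.0f ",
                     "(N50/total %.4f); %d scaffolds >= %.0f bp (%.1f%%)\n"),
              x$scaffold_count, x$total_length, x$n50, x$n50_over_total,
              x$scaffolds_over_threshold, x$threshold,
              100 * x$fraction_over_threshold))
  invisible(x)
}

#' Screen scaffolds for bacterial contaminants
#'
#' Eukaryotic poly-A selected RNA libraries leave bacterial scaffolds with
#' essentially zero RNA coverage; combined with elevated GC this flags
#' contaminant candidates. The full table is returned for blob-style
#' plotting regardless of flag.
#'
#' @param seqs A [sequence_set()] of scaffolds.
#' @param coverage Named numeric vector, scaffold to mean RNA coverage;
#'   scaffolds absent from it are treated as coverage 0.
#' @param gc_threshold Flag scaffolds with GC fraction strictly above this.
#' @param cov_threshold Flag scaffolds with coverage strictly below this.
#' @return data.frame with `scaffold`, `gc_fraction` (over ACGT bases
#'   only), `mean_rna_coverage`, `length`, `flagged_bacterial`.
#' @export
screen_contaminant_scaffolds <- function(seqs, coverage = numeric(),
                                         gc_threshold = 0.40,
                                         cov_threshold = 1) {
  s <- as.character(seqs)
  gc <- gc_fraction(seqs)
  cov <- rep(0, length(s))
  names(cov) <- names(seqs)
  shared <- intersect(names(coverage), names(cov))
  cov[shared] <- coverage[shared]
  out <- data.frame(scaffold = names(seqs),
                    gc_fraction = unname(gc),
                    mean_rna_coverage = unname(cov),
                    length = unname(nchar(s)))
  out$flagged_bacterial <- out$gc_fraction > gc_threshold &
    out$mean_rna_coverage < cov_threshold
  out
}
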