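#' Read a GFF3 annotation
#'
#' Parses gene / transcript / exon features (transcript aliases `mRNA` and
#' `transcript` are both accepted, as emitted by BRAKER2 or StringTie) into
#' an [annotation_set()]. GFF3's 1-based inclusive coordinates are converted
#' to the package's 0-based half-open convention at this boundary.
#'
#' @param path Path to a GFF3 file.
#' @return An [annotation_set()].
#' @details Transcripts whose `Parent` gene is absent, exons whose `Parent`
#'   transcript is absent, and genes without any exon-bearing transcript are
#'   structural errors naming the offending id. Duplicate gene ids are fatal.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent  # CharacterList
  first_parent <- vapply(parents, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))

  is_gene <- type == "gene"
  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"

  gene_ids <- ids[is_gene]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1])
  tx_ids <- ids[is_tx]
  if (anyDuplicated(tx_ids))
    stop("duplicate transcript id: ", tx_ids[duplicated(tx_ids)][1])

  tx_parent <- first_parent[is_tx]
  orphan_tx <- tx_ids[is.na(tx_parent) | !(tx_parent %in% gene_ids)]
  if (length(orphan_tx))
    stop("transcript(s) with unresolvable Parent gene: ",
         paste(utils::head(orphan_tx, 10), collapse = ", "))

  exon_parent <- first_parent[is_exon]
  orphan_ex <- which(is.na(exon_parent) | !(exon_parent %in% tx_ids))
  if (length(orphan_ex))
    stop("exon(s) with unresolvable Parent transcript near position ",
         GenomicRanges::start(gr[is_exon][orphan_ex[1]]))

  tx_gene <- stats::setNames(tx_parent, tx_ids)
  exon_gr <- gr[is_exon]
  exons <- data.frame(
    scaffold = as.character(GenomicRanges::seqnames(exon_gr)),
    start = GenomicRanges::start(exon_gr) - 1,  # to 0-based half-open
    end = as.numeric(GenomicRanges::end(exon_gr)),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(exon_gr))),
    tx_id = exon_parent,
    gene_id = unname(tx_gene[exon_parent]))

  bare <- setdiff(gene_ids, exons$gene_id)
  if (length(bare))
    stop("gene(s) without exon children: ",
         paste(utils::head(bare, 10), collapse = ", "))
  annotation_set(exons)
}

#' Write an annotation as GFF3
#'
#' Emits gene, mRNA and exon rows with 1-based inclusive coordinates and
#' deterministic ordering (scaffold, span start, gene id; transcripts and
#' exons nested under their gene). `read_gff(write_gff(x))` round-trips to
#' an equal annotation.
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff <- function(ann, path, source = "glassarch") {
  stopifnot(inherits(ann, "annotation_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!nrow(ann$genes)) return(invisible(path))

  genes <- ann$genes[order(ann$genes$scaffold, ann$genes$start,
                           ann$genes$gene_id), , drop = FALSE]
  tx_by_gene <- split(ann$transcripts, ann$transcripts$gene_id)
  ex_by_tx <- split(ann$exons, ann$exons$tx_id)
  fmt <- function(scaf, src, type, start, end, strand, attrs)
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
            scaf, src, type, as.integer(start + 1), as.integer(end),
            strand, attrs)
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    txs <- tx_by_gene[[g$gene_id]]
    txs <- txs[order(txs$start, txs$tx_id), , drop = FALSE]
    strand_g <- txs$strand[1]
    lines <- c(lines, fmt(g$scaffold, source, "gene", g$start, g$end,
                          strand_g, paste0("ID=", g$gene_id)))
    for (j in seq_len(nrow(txs))) {
      tx <- txs[j, ]
      lines <- c(lines, fmt(tx$scaffold, source, "mRNA", tx$start, tx$end,
                            tx$strand,
                            paste0("ID=", tx$tx_id, ";Parent=", tx$gene_id)))
      exs <- ex_by_tx[[tx$tx_id]]
      exs <- exs[order(exs$start), , drop = FALSE]
      lines <- c(lines, fmt(exs$scaffold, source, "exon", exs$start, exs$end,
                            exs$strand, paste0("Parent=", tx$tx_id)))
    }
  }
  writeLines(lines, con)
  invisible(path)
}
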