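#' Gene annotation container
#'
#' An `annotation_set` holds a gene / transcript / exon hierarchy with
#' scaffold coordinates. All coordinates are 0-based half-open internally;
#' GFF3 input/output converts at the boundary. It is built from a flat exon
#' table and carries derived per-transcript and per-gene tables:
#'
#' * `$exons`: `scaffold`, `start`, `end`, `strand`, `tx_id`, `gene_id`
#'   (one row per exon, sorted within transcript)
#' * `$transcripts`: `tx_id`, `gene_id`, `scaffold`, `strand`, `n_exons`,
#'   `exonic_bp` (summed exon lengths), `start`, `end`
#' * `$genes`: `gene_id`, `scaffold`, `start`, `end` (span = envelope over
#'   all transcripts), `n_tx`
#'
#' @param exons data.frame with columns `scaffold`, `start`, `end`,
#'   `strand`, `tx_id`, `gene_id`. Coordinates 0-based half-open.
#' @return An object of class `annotation_set`.
#' @examples
#' ex <- data.frame(scaffold = "s1", start = c(99, 799), end = c(200, 900),
#'                  strand = "+", tx_id = "t1", gene_id = "g1")
#' ann <- annotation_set(ex)
#' ann$genes
#' @export
annotation_set <- function(exons) {
  required <- c("scaffold", "start", "end", "strand", "tx_id", "gene_id")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols))
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  exons <- as.data.frame(exons)[required]
  exons$scaffold <- as.character(exons$scaffold)
  exons$strand <- as.character(exons$strand)
  exons$tx_id <- as.character(exons$tx_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)

  if (nrow(exons)) {
    if (any(exons$start < 0)) stop("negative exon start")
    if (any(exons$end <= exons$start)) stop("exon end must exceed start")
    if (!all(exons$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
    exons <- exons[order(exons$scaffold, exons$gene_id, exons$tx_id, exons$start), ,
                   drop = FALSE]
    rownames(exons) <- NULL
    # one scaffold and strand per transcript; exons disjoint within transcript
    by_tx <- split(seq_len(nrow(exons)), exons$tx_id)
    for (idx in by_tx) {
      if (length(unique(exons$scaffold[idx])) != 1L)
        stop("transcript ", exons$tx_id[idx[1]], " spans multiple scaffolds")
      if (length(unique(exons$strand[idx])) != 1L)
        stop("transcript ", exons$tx_id[idx[1]], " mixes strands")
      if (length(idx) > 1L) {
        s <- exons$start[idx]; e <- exons$end[idx]
        if (any(s[-1] < e[-length(e)]))
          stop("transcript ", exons$tx_id[idx[1]], " has overlapping exons")
      }
    }
    # a transcript belongs to exactly one gene; a gene to one scaffold
    tx_gene <- unique(exons[c("tx_id", "gene_id")])
    if (anyDuplicated(tx_gene$tx_id))
      stop("transcript id assigned to multiple genes: ",
           tx_gene$tx_id[duplicated(tx_gene$tx_id)][1])
    gene_scaf <- unique(exons[c("gene_id", "scaffold")])
    if (anyDuplicated(gene_scaf$gene_id))
      stop("gene on multiple scaffolds: ",
           gene_scaf$gene_id[duplicated(gene_scaf$gene_id)][1])
  }

  transcripts <- .summarise_tx(exons)
  genes <- .summarise_genes(transcripts)
  structure(list(exons = exons, transcripts = transcripts, genes = genes),
            class = "annotation_set")
}

.summarise_tx <- function(exons) {
  if (!nrow(exons))
    return(data.frame(tx_id = character(), gene_id = character(),
                      scaffold = character(), strand = character(),
                      n_exons = integer(), exonic_bp = numeric(),
                      start = numeric(), end = numeric()))
  f <- factor(exons$tx_id, levels = unique(exons$tx_id))
  out <- data.frame(
    tx_id = levels(f),
    gene_id = exons$gene_id[!duplicated(f)],
    scaffold = exons$scaffold[!duplicated(f)],
    strand = exons$strand[!duplicated(f)],
    n_exons = as.integer(tabulate(f)),
    exonic_bp = as.numeric(tapply(exons$end - exons$start, f, sum)),
    start = as.numeric(tapply(exons$start, f, min)),
    end = as.numeric(tapply(exons$end, f, max)))
  rownames(out) <- NULL
  out
}

.summarise_genes <- function(tx) {
  if (!nrow(tx))
    return(data.frame(gene_id = character(), scaffold = character(),
                      start = numeric(), end = numeric(), n_tx = integer()))
  f <- factor(tx$gene_id, levels = unique(tx$gene_id))
  out <- data.frame(
    gene_id = levels(f),
    scaffold = tx$scaffold[!duplicated(f)],
    start = as.numeric(tapply(tx$start, f, min)),
    end = as.numeric(tapply(tx$end, f, max)),
    n_tx = as.integer(tabulate(f)))
  out <- out[order(out$scaffold, out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$exons), "exons on",
      length(unique(x$genes$scaffold)), "scaffold(s)\n")
  invisible(x)
}

#' Intron table of an annotation
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' in 0-based half-open coordinates.
#'
#' @param ann An `annotation_set`.
#' @return data.frame with `scaffold`, `start`, `end`, `strand`, `tx_id`,
#'   `gene_id`; one row per intron per transcript (not deduplicated).
#' @export
ann_introns <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  ex <- ann$exons
  multi <- ann$transcripts$tx_id[ann$transcripts$n_exons > 1L]
  ex <- ex[ex$tx_id %in% multi, , drop = FALSE]
  if (!nrow(ex))
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      tx_id = character(), gene_id = character()))
  # exons are sorted by start within tx after construction
  keep <- ex$tx_id[-1] == ex$tx_id[-nrow(ex)]
  data.frame(scaffold = ex$scaffold[-nrow(ex)][keep],
             start = ex$end[-nrow(ex)][keep],
             end = ex$start[-1][keep],
             strand = ex$strand[-nrow(ex)][keep],
             tx_id = ex$tx_id[-nrow(ex)][keep],
             gene_id = ex$gene_id[-nrow(ex)][keep])
}

#' Sequence set container
#'
#' A named character vector of residue strings with an alphabet tag, the
#' in-memory form of a FASTA file.
#'
#' @param seqs named character vector; names unique, sequences non-empty.
#' @param alphabet `"nt"` or `"aa"`.
#' @return Object of class `sequence_set` (a named character vector with an
#'   `alphabet` attribute).
#' @export
sequence_set <- function(seqs, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  seqs <- unlist(as.list(seqs))
  if (length(seqs)) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("all sequences must be named")
    if (anyDuplicated(names(seqs)))
      stop("duplicate sequence id: ", names(seqs)[duplicated(names(seqs))][1])
    if (any(!nzchar(seqs)))
      stop("empty sequence: ", names(seqs)[!nzchar(seqs)][1])
  }
  structure(toupper(seqs), alphabet = alphabet, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set (", attr(x, "alphabet"), "): ", length(x),
      " sequences, ", sum(nchar(x)), " residues\n", sep = "")
  invisible(x)
}

#' @export
as.character.sequence_set <- function(x, ...) {
  out <- unclass(x)
  attr(out, "alphabet") <- NULL
  out
}

#' @export
`[.sequence_set` <- function(x, i) {
  structure(unclass(x)[i], alphabet = attr(x, "alphabet"),
            class = "sequence_set")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
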