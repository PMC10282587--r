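#' Read a 12-column tabular protein hit table
#'
#' The BLAST/DIAMOND `-outfmt 6` layout: query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#' Self-hits (query == subject) are dropped.
#'
#' @param path Tab-separated hit file (no header).
#' @param query_genes,subject_genes Optional [annotation_set()]s; when
#'   given, every query/subject id must resolve to a gene id there.
#' @return data.frame of class `hit_table` with the 12 columns.
#' @export
read_hit_table <- function(path, query_genes = NULL, subject_genes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(hit_table(NULL))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("expected 12 tab-separated columns at line ", bad[1],
         " (found ", lengths(fields)[bad[1]], ")")
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  hits <- data.frame(query = m[, 1], subject = m[, 2],
                     pident = as.numeric(m[, 3]),
                     length = as.integer(m[, 4]),
                     mismatch = as.integer(m[, 5]),
                     gapopen = as.integer(m[, 6]),
                     qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                     sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                     evalue = as.numeric(m[, 11]),
                     bitscore = as.numeric(m[, 12]))
  names(hits) <- cols
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  for (side in c("query", "subject")) {
    genes <- if (side == "query") query_genes else subject_genes
    if (!is.null(genes)) {
      unknown <- setdiff(hits[[side]], genes$genes$gene_id)
      if (length(unknown))
        stop("unresolvable ", side, " id(s): ",
             paste(utils::head(unknown, 10), collapse = ", "))
    }
  }
  hit_table(hits)
}

#' Construct a hit table from a data.frame
#'
#' @param hits data.frame with at least `query`, `subject`, `evalue`,
#'   `bitscore` columns, or `NULL` for an empty table.
#' @return data.frame of class `hit_table`.
#' @export
hit_table <- function(hits = NULL) {
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(query = character(), subject = character(),
                       pident = numeric(), length = integer(),
                       mismatch = integer(), gapopen = integer(),
                       qstart = integer(), qend = integer(),
                       sstart = integer(), send = integer(),
                       evalue = numeric(), bitscore = numeric())
  }
  need <- c("query", "subject", "evalue", "bitscore")
  if (!all(need %in% names(hits)))
    stop("hit table needs columns: ", paste(need, collapse = ", "))
  if (nrow(hits) && (any(hits$evalue < 0) || any(hits$bitscore < 0)))
    stop("negative evalue or bitscore")
  rownames(hits) <- NULL
  class(hits) <- c("hit_table", "data.frame")
  hits
}

#' Write a hit table in the 12-column tabular format
#'
#' @param hits A `hit_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- as.data.frame(hits)
  for (col in setdiff(cols, names(df))) df[[col]] <- 0
  utils::write.table(format(df[cols], trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a differential-expression result table
#'
#' Consumes (never computes) a DESeq2-style TSV. Missing adjusted p-values
#' (`NA`) stay missing rather than becoming 0.
#'
#' @param path TSV file with a header.
#' @param gene_col,log2fc_col,padj_col Column names to use.
#' @return data.frame with `gene`, `log2fc`, `padj`.
#' @export
read_expression_table <- function(path, gene_col = "gene",
                                  log2fc_col = "log2fc",
                                  padj_col = "padj") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(gene_col, log2fc_col, padj_col))
    if (!col %in% names(df))
      stop("expression table lacks required column '", col, "'")
  out <- data.frame(gene = as.character(df[[gene_col]]),
                    log2fc = as.numeric(df[[log2fc_col]]),
                    padj = suppressWarnings(as.numeric(df[[padj_col]])))
  if (any(!is.na(out$padj) & (out$padj < 0 | out$padj > 1)))
    stop("padj outside [0, 1]")
  out
}
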