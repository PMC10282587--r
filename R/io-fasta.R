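#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @param alphabet `"nt"` or `"aa"` tag for the resulting [sequence_set()].
#' @return A [sequence_set()]; ids are the header token up to the first
#'   whitespace and sequences are uppercased. Duplicate ids and empty
#'   records are errors.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  seqs <- as.character(ss)
  names(seqs) <- ids
  if (any(!nzchar(seqs)))
    stop("empty record: ", ids[!nzchar(seqs)][1])
  sequence_set(seqs, alphabet = alphabet)
}

#' Write a sequence set as FASTA
#'
#' @param seqs A [sequence_set()] or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (!length(seqs)) {
    cat("", file = path)
    return(invisible(path))
  }
  ss <- Biostrings::BStringSet(stats::setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' GC fraction of nucleotide sequences
#'
#' Computed over unambiguous A/C/G/T bases only, so assembly gaps (N runs)
#' do not dilute the estimate.
#'
#' @param seqs A [sequence_set()] or character vector of nucleotide strings.
#' @return Numeric vector of GC fractions in `[0, 1]` (NaN for sequences
#'   with no ACGT base).
#' @export
gc_fraction <- function(seqs) {
  s <- toupper(as.character(seqs))
  counts <- t(vapply(s, function(x) {
    tab <- table(strsplit(x, "")[[1]])
    c(gc = sum(tab[names(tab) %in% c("G", "C")]),
      at = sum(tab[names(tab) %in% c("A", "T")]))
  }, c(gc = 0, at = 0)))
  out <- counts[, "gc"] / (counts[, "gc"] + counts[, "at"])
  stats::setNames(as.numeric(out), names(seqs))
}
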