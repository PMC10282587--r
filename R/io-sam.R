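#' Read a text SAM file of long-read alignments
#'
#' Parses the 11 mandatory SAM columns into an alignment table. Unmapped
#' records (FLAG 0x4) are always skipped; secondary (0x100) and
#' supplementary (0x800) records are skipped by default so each read
#' contributes one alignment.
#'
#' @param path SAM text file.
#' @param keep_secondary Keep secondary/supplementary records.
#' @return data.frame of class `aligned_reads` with columns `name`, `flag`,
#'   `scaffold`, `pos` (0-based leftmost mapped base), `strand` (`+`/`-`
#'   from FLAG 0x10), `cigar`, `seq` (`NA` when the record stores `*`).
#'   CIGAR query-consuming lengths (M, I, S, =, X) are checked against the
#'   stored sequence length.
#' @export
read_sam <- function(path, keep_secondary = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.empty_aligned_reads())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("SAM record with fewer than 11 fields at alignment line ",
         which(nf < 11)[1])
  flag <- as.integer(vapply(fields, `[[`, "", 2))
  keep <- bitwAnd(flag, 4L) == 0L
  if (!keep_secondary)
    keep <- keep & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  fields <- fields[keep]; flag <- flag[keep]
  if (!length(fields)) return(.empty_aligned_reads())
  out <- data.frame(
    name = vapply(fields, `[[`, "", 1),
    flag = flag,
    scaffold = vapply(fields, `[[`, "", 3),
    pos = as.numeric(vapply(fields, `[[`, "", 4)) - 1,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    cigar = vapply(fields, `[[`, "", 6),
    seq = vapply(fields, `[[`, "", 10))
  out$seq[out$seq == "*"] <- NA_character_
  bad <- grepl("[^0-9MIDNSHP=X]", out$cigar) | out$cigar == "*"
  if (any(bad))
    stop("unparseable CIGAR for read ", out$name[bad][1])
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    out$cigar, after.soft.clipping = FALSE)
  has_seq <- !is.na(out$seq)
  if (any(has_seq & nchar(out$seq) != qlen))
    stop("CIGAR query length disagrees with SEQ for read ",
         out$name[has_seq & nchar(out$seq) != qlen][1])
  class(out) <- c("aligned_reads", "data.frame")
  out
}

.empty_aligned_reads <- function() {
  out <- data.frame(name = character(), flag = integer(),
                    scaffold = character(), pos = numeric(),
                    strand = character(), cigar = character(),
                    seq = character())
  class(out) <- c("aligned_reads", "data.frame")
  out
}

# split CIGAR strings into parallel lists of op letters and lengths
.cigar_ops <- function(cigar) {
  list(ops = GenomicAlignments::explodeCigarOps(cigar),
       lens = GenomicAlignments::explodeCigarOpLengths(cigar))
}
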