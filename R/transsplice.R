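#' Extract 5' soft-clip events from long-read alignments
#'
#' A trans-spliced leader cannot map as a genomic exon, so full-length
#' cDNA reads carry it as a soft clip at the transcript 5' end. For a
#' plus-strand alignment that is a leading `S` operation; for a
#' minus-strand alignment it is a trailing `S` operation whose sequence is
#' reverse-complemented here, so every returned clip reads 5'->3' in
#' transcript orientation and ends at the base adjacent to the first
#' aligned base. Hard clips carry no sequence and never yield events.
#'
#' @param reads `aligned_reads` from [read_sam()].
#' @param min_len,max_len Clip length window (bp); events outside it are
#'   discarded.
#' @return data.frame of class `clip_events`: `name`, `scaffold`,
#'   `clip_length`, `clip_seq` (`NA` when the record stored no sequence),
#'   `strand`.
#' @export
extract_clips <- function(reads, min_len = 20, max_len = 60) {
  stopifnot(is.data.frame(reads))
  empty <- data.frame(name = character(), scaffold = character(),
                      clip_length = integer(), clip_seq = character(),
                      strand = character())
  class(empty) <- c("clip_events", "data.frame")
  if (!nrow(reads)) return(empty)
  cig <- .cigar_ops(reads$cigar)
  first_op <- vapply(cig$ops, `[`, "", 1)
  last_op <- vapply(cig$ops, function(x) x[length(x)], "")
  first_len <- vapply(cig$lens, `[`, 0L, 1)
  last_len <- vapply(cig$lens, function(x) x[length(x)], 0L)

  plus <- reads$strand == "+"
  has_clip <- ifelse(plus, first_op == "S", last_op == "S")
  clip_len <- ifelse(plus, first_len, last_len)
  keep <- has_clip & clip_len >= min_len & clip_len <= max_len
  if (!any(keep)) return(empty)

  r <- reads[keep, , drop = FALSE]
  len <- clip_len[keep]
  seq_known <- !is.na(r$seq)
  if (any(seq_known & len > nchar(r$seq)))
    stop("soft clip longer than query for read ",
         r$name[seq_known & len > nchar(r$seq)][1])
  clip_seq <- rep(NA_character_, nrow(r))
  p <- r$strand == "+" & seq_known
  m <- r$strand == "-" & seq_known
  if (any(p)) clip_seq[p] <- substr(r$seq[p], 1, len[p])
  if (any(m))
    clip_seq[m] <- .revcomp(substr(r$seq[m],
                                   nchar(r$seq[m]) - len[m] + 1,
                                   nchar(r$seq[m])))
  out <- data.frame(name = r$name, scaffold = r$scaffold,
                    clip_length = as.integer(len), clip_seq = clip_seq,
                    strand = r$strand)
  rownames(out) <- NULL
  class(out) <- c("clip_events", "data.frame")
  out
}

#' Clip-length histogram with windowed peak
#'
#' @param events `clip_events` from [extract_clips()].
#' @param window Length window (bp) searched for the modal peak.
#' @return Object of class `clip_histogram`: `counts` (named integer
#'   vector, length -> reads), `peak_length` (modal length within the
#'   window, ties broken toward the smaller length; `NA` when no event
#'   falls in the window), `window`.
#' @export
clip_histogram <- function(events, window = c(20, 60)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  lens <- events$clip_length
  counts <- table(factor(lens, levels = if (length(lens))
    seq(min(lens), max(lens)) else integer(0)))
  counts <- stats::setNames(as.integer(counts),
                            names(counts))
  in_win <- lens[lens >= window[1] & lens <= window[2]]
  peak <- if (length(in_win)) {
    tab <- table(in_win)
    as.integer(names(tab)[which.max(tab)])  # which.max: first = smallest
  } else NA_integer_
  structure(list(counts = counts, peak_length = peak, window = window),
            class = "clip_histogram")
}

#' @export
print.clip_histogram <- function(x, ...) {
  cat("clip_histogram:", sum(x$counts), "events; peak",
      x$peak_length, "bp in window [", x$window[1], ",", x$window[2], "]\n")
  invisible(x)
}

#' @export
plot.clip_histogram <- function(x, ...) {
  lens <- as.integer(names(x$counts))
  graphics::barplot(x$counts, names.arg = lens, space = 0, border = NA,
                    xlab = "soft-clip length (bp)", ylab = "reads", ...)
  invisible(x)
}

#' Leader consensus and frequency statistics
#'
#' Clips with length within `tolerance` of the peak are aligned at their
#' 3' (alignment-adjacent) ends -- a fixed leader presents with a ragged
#' 5' end when partially degraded -- and a per-position majority consensus
#' over the peak-length window is taken.
#'
#' @param events `clip_events` carrying sequences.
#' @param peak Peak clip length (bp), e.g. from [clip_histogram()].
#' @param tolerance Accept clip lengths in `peak +/- tolerance` (bp).
#' @param total_mapped Total mapped reads the events were drawn from,
#'   the denominator of `leader_read_fraction`.
#' @return Object of class `leader_motif`: `consensus`,
#'   `consensus_length`, `n_leader_reads`, `leader_read_fraction`
#'   (qualifying events / total mapped reads), `top_leader_share`
#'   (frequency of the most common exact clip among qualifying events).
#' @export
leader_consensus <- function(events, peak, tolerance = 3, total_mapped) {
  stopifnot(total_mapped >= nrow(events))
  q <- events[!is.na(events$clip_seq) &
                events$clip_length >= peak - tolerance &
                events$clip_length <= peak + tolerance, , drop = FALSE]
  if (!nrow(q))
    stop("no qualifying clip events near peak ", peak,
         " bp: insufficient evidence for a leader")
  # right-align: position i counts from the 3' end (i = 1 is adjacent to
  # the alignment start); consensus emitted 5'->3'
  mat <- matrix(NA_character_, nrow = nrow(q), ncol = peak)
  for (i in seq_len(nrow(q))) {
    ch <- strsplit(q$clip_seq[i], "")[[1]]
    n <- min(length(ch), peak)
    mat[i, seq_len(n)] <- rev(ch)[seq_len(n)]
  }
  consensus <- vapply(seq_len(peak), function(j) {
    tab <- sort(table(mat[, j]), decreasing = TRUE)
    if (!length(tab)) return("N")
    top <- names(tab)[tab == max(tab)]
    sort(top)[1]  # deterministic tie-break
  }, "")
  tab <- sort(table(q$clip_seq), decreasing = TRUE)
  structure(list(consensus = paste(rev(consensus), collapse = ""),
                 consensus_length = peak,
                 n_leader_reads = nrow(q),
                 leader_read_fraction = nrow(q) / total_mapped,
                 top_leader_share = as.numeric(tab[1]) / nrow(q)),
            class = "leader_motif")
}

#' @export
print.leader_motif <- function(x, ...) {
  cat("leader_motif:", x$consensus, "\n  ",
      x$n_leader_reads, "leader reads;",
      sprintf("%.1f%% of mapped reads; top exact leader %.1f%%\n",
              100 * x$leader_read_fraction, 100 * x$top_leader_share))
  invisible(x)
}
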