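.apply_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(bases, b), 1), "")
  }
  paste(ch, collapse = "")
}

#' Simulate long cDNA reads with a trans-spliced leader
#'
#' Emits a text SAM file of full-length cDNA alignments against a random
#' genome. A tunable fraction of reads carries a fixed 5' leader, which
#' the emitted alignment soft-clips in full: a leading `S` for plus-strand
#' alignments, a trailing `S` (with the stored sequence
#' reverse-complemented, as SAM requires) for minus-strand ones.
#' Substitution errors are applied across the whole read, leader
#' included, emulating noisy long reads.
#'
#' @param seed Integer seed.
#' @param path Output SAM path.
#' @param n_reads Mapped reads to emit.
#' @param leader_fraction Fraction of reads carrying the leader.
#' @param leader Leader sequence; default a random 37-mer drawn under the
#'   seed.
#' @param error_rate Per-base substitution probability.
#' @param minus_fraction Fraction of transcripts on the genomic minus
#'   strand.
#' @param n_scaffolds,scaffold_length Genome shape.
#' @param read_length Range of aligned (genomic) read lengths.
#' @return List with `sam` (the path) and `truth`: `leader`, per-read
#'   `has_leader` flags, `n_mapped`, `leader_read_fraction`.
#' @export
simulate_leader_reads <- function(seed, path = tempfile(fileext = ".sam"),
                                  n_reads = 2000, leader_fraction = 0.04,
                                  leader = NULL, error_rate = 0.05,
                                  minus_fraction = 0.5, n_scaffolds = 2,
                                  scaffold_length = 50000,
                                  read_length = c(500, 2000)) {
  stopifnot(leader_fraction >= 0, leader_fraction <= 1)
  .with_seed(seed, {
    if (is.null(leader)) leader <- .random_dna(37, 0.4)
    genome <- vapply(seq_len(n_scaffolds), function(i)
      .random_dna(scaffold_length, 0.4), "")
    names(genome) <- sprintf("scaf%02d", seq_len(n_scaffolds))

    has_leader <- stats::runif(n_reads) < leader_fraction
    lines <- c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(genome), scaffold_length))
    recs <- character(n_reads)
    for (i in seq_len(n_reads)) {
      sc <- sample(n_scaffolds, 1)
      len <- round(stats::runif(1, read_length[1], read_length[2]))
      start <- sample(scaffold_length - len, 1)  # 1-based
      body <- substr(genome[sc], start, start + len - 1)
      minus <- stats::runif(1) < minus_fraction
      # read in transcript orientation (cDNA 5'->3')
      tx_body <- if (minus) .revcomp(body) else body
      read <- paste0(if (has_leader[i]) leader else "", tx_body)
      read <- .apply_errors(read, error_rate)
      L <- if (has_leader[i]) nchar(leader) else 0L
      if (minus) {
        seq_out <- .revcomp(read)
        cigar <- if (L) sprintf("%dM%dS", len, L) else sprintf("%dM", len)
        flag <- 16L
      } else {
        seq_out <- read
        cigar <- if (L) sprintf("%dS%dM", L, len) else sprintf("%dM", len)
        flag <- 0L
      }
      recs[i] <- sprintf("read%05d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                         i, flag, names(genome)[sc], start, cigar, seq_out)
    }
    writeLines(c(lines, recs), path)
    list(sam = path,
         truth = list(leader = leader, has_leader = has_leader,
                      n_mapped = n_reads,
                      leader_read_fraction = mean(has_leader)))
  })
}

# background residue frequencies of a generic well-annotated proteome
.BACKGROUND_AA_FREQ <- local({
  f <- c(A = 8.3, R = 5.5, N = 4.0, D = 5.4, C = 1.4, E = 6.7, Q = 3.9,
         G = 7.1, H = 2.2, I = 5.9, L = 9.6, K = 5.8, M = 2.4, F = 3.8,
         P = 4.7, S = 6.6, T = 5.3, W = 1.1, Y = 2.9, V = 6.8)
  f / sum(f)
})

#' Simulate a proteome with planted compositional bias
#'
#' Draws a background reference proteome and a study proteome from the
#' same residue frequencies, then plants a fraction of study proteins
#' whose frequency of one biomineralization-type residue exceeds the
#' reference 99th percentile by construction. A matching expression table
#' gives planted proteins strong upregulation and tiny adjusted p-values,
#' and null proteins uniform ones; the differential-expression model
#' itself is out of scope, so p-values are drawn directly.
#'
#' @param seed Integer seed.
#' @param n_proteins Study proteome size.
#' @param n_reference Reference proteome size.
#' @param planted_fraction Fraction of study proteins planted biased
#'   (in `[0, 0.2]`).
#' @param planted_residues Residues the planted bias draws from.
#' @param bias_delta Margin above the reference P99 frequency.
#' @param q,min_len Percentile and length floor used for the internal
#'   reference table the planting is calibrated against.
#' @param length_meanlog,length_sdlog Log-normal protein length
#'   parameters.
#' @return List with `proteome`, `reference` ([sequence_set()]s), `expr`
#'   (data.frame `gene`, `log2fc`, `padj`) and `truth` (planted ids and
#'   their biased residues).
#' @export
simulate_proteome <- function(seed, n_proteins = 1000, n_reference = 1000,
                              planted_fraction = 0.02,
                              planted_residues = c("D", "E", "H", "P",
                                                   "S", "T"),
                              bias_delta = 0.08, q = 99, min_len = 50,
                              length_meanlog = log(300),
                              length_sdlog = 0.4) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 0.2)
  .with_seed(seed, {
    rlen <- function(n) pmax(min_len,
                             round(stats::rlnorm(n, length_meanlog,
                                                 length_sdlog)))
    draw <- function(len, freq = .BACKGROUND_AA_FREQ)
      paste(sample(names(freq), len, replace = TRUE, prob = freq),
            collapse = "")
    reference <- vapply(rlen(n_reference), draw, "")
    names(reference) <- sprintf("ref%05d", seq_len(n_reference))
    reference <- sequence_set(reference, "aa")
    p99 <- reference_percentiles(reference, q = q, min_len = min_len)

    n_planted <- round(planted_fraction * n_proteins)
    planted_idx <- if (n_planted) sort(sample(n_proteins, n_planted))
      else integer(0)
    lens <- rlen(n_proteins)
    prots <- character(n_proteins)
    planted_aa <- character(n_proteins)
    for (i in seq_len(n_proteins)) {
      if (i %in% planted_idx) {
        aa <- sample(planted_residues, 1)
        target <- min(p99$values[aa] + bias_delta, 0.9)
        n_bias <- ceiling(target * lens[i])
        rest_freq <- .BACKGROUND_AA_FREQ[names(.BACKGROUND_AA_FREQ) != aa]
        rest <- draw(lens[i] - n_bias, rest_freq / sum(rest_freq))
        ch <- c(rep(aa, n_bias), strsplit(rest, "")[[1]])
        prots[i] <- paste(sample(ch), collapse = "")
        planted_aa[i] <- aa
      } else {
        prots[i] <- draw(lens[i])
      }
    }
    names(prots) <- sprintf("prot%05d", seq_len(n_proteins))
    planted_ids <- names(prots)[planted_idx]

    expr <- data.frame(gene = names(prots),
                       log2fc = stats::rnorm(n_proteins, 0, 1),
                       padj = stats::runif(n_proteins))
    expr$log2fc[planted_idx] <- stats::rnorm(n_planted, 5, 0.5)
    expr$padj[planted_idx] <- 10^(-stats::runif(n_planted, 5, 9))

    list(proteome = sequence_set(prots, "aa"), reference = reference,
         expr = expr,
         truth = list(planted_ids = planted_ids,
                      planted_aa = stats::setNames(
                        planted_aa[planted_idx], planted_ids),
                      percentiles = p99))
  })
}

#' Simulate an assembly metric table
#'
#' Random values for the seven standard evaluation metrics; with
#' `dominating = TRUE` one assembly is made strictly best on every metric
#' (respecting each metric's direction) and recorded as truth.
#'
#' @param seed Integer seed.
#' @param n_assemblies Number of assemblies.
#' @param dominating Plant a dominating assembly.
#' @return List with `table` (data.frame, `assembly` + 7 metric columns)
#'   and `truth` (`best` id or `NA`).
#' @export
simulate_assembly_metrics <- function(seed, n_assemblies = 8,
                                      dominating = TRUE) {
  stopifnot(n_assemblies >= 1)
  .with_seed(seed, {
    tab <- data.frame(
      assembly = sprintf("asm%02d", seq_len(n_assemblies)),
      n50 = round(stats::runif(n_assemblies, 1e6, 5e6)),
      size_delta_pct = round(stats::runif(n_assemblies, 0.5, 20), 2),
      mean_scaffold_len = round(stats::runif(n_assemblies, 1e5, 1e6)),
      scaffold_count = sample(50:2000, n_assemblies, replace = TRUE),
      busco_single_complete = round(stats::runif(n_assemblies, 70, 98), 1),
      rna_map_pct = round(stats::runif(n_assemblies, 50, 98), 1),
      dna_map_pct = round(stats::runif(n_assemblies, 80, 99), 1))
    best <- NA_character_
    if (dominating) {
      w <- sample(n_assemblies, 1)
      best <- tab$assembly[w]
      for (i in seq_len(nrow(default_rank_scheme()))) {
        m <- default_rank_scheme()$metric[i]
        if (default_rank_scheme()$direction[i] == "higher_better")
          tab[[m]][w] <- max(tab[[m]]) + 1
        else tab[[m]][w] <- max(0, min(tab[[m]]) - 1)
      }
    }
    list(table = tab, truth = list(best = best))
  })
}
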