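# run expr under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (has_old) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

.random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a compact annotated genome with nested genes
#'
#' Emulates the architecture of a compact animal genome: densely packed
#' genes, short log-normal introns, a tunable single-exon fraction, and a
#' planted fraction of nested genes. Planted nested genes are single-exon
#' and strictly interior to one host intron with margins of at least
#' 10 bp, so nested-gene recovery is unambiguous and exact. Optional
#' contaminant scaffolds get elevated GC, no genes and zero RNA coverage.
#'
#' @param seed Integer seed; outputs are byte-identical per seed.
#' @param n_genes Total genes including nested ones.
#' @param n_scaffolds Scaffolds carrying genes.
#' @param single_exon_fraction Probability a non-nested gene is
#'   single-exon.
#' @param nested_fraction Fraction of genes planted inside host introns
#'   (in `[0, 0.5]`).
#' @param intron_meanlog,intron_sdlog Log-normal intron length
#'   parameters; the default median of about 300 bp sits between the
#'   short-intron regimes seen in compact sponge genomes.
#' @param gc GC fraction of normal scaffolds.
#' @param n_contaminant Contaminant scaffolds to append.
#' @param contaminant_gc,contaminant_length Their GC and length.
#' @return List with `seqs` ([sequence_set()]), `ann`
#'   ([annotation_set()]), `coverage` (named mean RNA coverage per
#'   scaffold; 0 for contaminants) and `truth` (nested gene ids, host
#'   pairs, single-exon transcript count, contaminant scaffold ids).
#' @export
simulate_annotated_genome <- function(seed, n_genes = 500, n_scaffolds = 4,
                                      single_exon_fraction = 0.3,
                                      nested_fraction = 0.12,
                                      intron_meanlog = log(300),
                                      intron_sdlog = 0.6,
                                      gc = 0.36, n_contaminant = 0,
                                      contaminant_gc = 0.55,
                                      contaminant_length = 20000) {
  stopifnot(nested_fraction >= 0, nested_fraction <= 0.5, n_genes >= 0)
  .with_seed(seed, {
    n_nested <- round(nested_fraction * n_genes)
    n_top <- n_genes - n_nested
    single <- stats::runif(n_top) < single_exon_fraction
    multi_idx <- which(!single)
    if (n_nested > length(multi_idx))
      stop("infeasible: ", n_nested, " nested genes need as many ",
           "multi-exon hosts but only ", length(multi_idx), " available")
    hosts <- if (n_nested) sort(sample(multi_idx, n_nested)) else integer(0)
    scaffold_of <- sort(rep_len(seq_len(n_scaffolds), n_top))

    exon_rows <- vector("list", n_genes)
    gid <- 0L
    truth_pairs <- list()
    pos <- stats::setNames(rep(0, n_scaffolds), seq_len(n_scaffolds))
    for (i in seq_len(n_top)) {
      sc <- scaffold_of[i]
      scaf <- sprintf("scaf%02d", sc)
      gid <- gid + 1L
      gene <- sprintf("g%04d", gid)
      tx <- paste0(gene, ".t1")
      strand <- sample(c("+", "-"), 1)
      start <- pos[sc] + round(stats::runif(1, 100, 800))
      nested_here <- i %in% hosts
      if (single[i]) {
        len <- pmin(pmax(round(stats::rlnorm(1, log(600), 0.5)), 200), 5000)
        ex <- data.frame(scaffold = scaf, start = start, end = start + len,
                         strand = strand, tx_id = tx, gene_id = gene)
      } else {
        k <- sample(2:5, 1)
        exon_len <- round(stats::runif(k, 100, 400))
        intron_len <- pmax(round(stats::rlnorm(k - 1, intron_meanlog,
                                               intron_sdlog)), 30)
        guest <- NULL
        if (nested_here) {
          glen <- round(stats::runif(1, 200, 800))
          lmar <- sample(10:50, 1); rmar <- sample(10:50, 1)
          intron_len[1] <- glen + lmar + rmar
          guest <- c(len = glen, lmar = lmar)
        }
        starts <- start + cumsum(c(0, (exon_len + c(intron_len, 0))[-k]))
        ex <- data.frame(scaffold = scaf, start = starts,
                         end = starts + exon_len, strand = strand,
                         tx_id = tx, gene_id = gene)
        if (!is.null(guest)) {
          gid <- gid + 1L
          ngene <- sprintf("g%04d", gid)
          gstart <- ex$end[1] + guest["lmar"]
          exon_rows[[gid]] <- data.frame(
            scaffold = scaf, start = unname(gstart),
            end = unname(gstart + guest["len"]),
            strand = sample(c("+", "-"), 1),
            tx_id = paste0(ngene, ".t1"), gene_id = ngene)
          truth_pairs[[length(truth_pairs) + 1]] <-
            data.frame(nested_gene = ngene, host_gene = gene)
        }
      }
      exon_rows[[if (nested_here) gid - 1L else gid]] <- ex
      pos[sc] <- max(ex$end)
    }
    exons <- do.call(rbind, exon_rows[!vapply(exon_rows, is.null, TRUE)])
    ann <- annotation_set(if (is.null(exons))
      data.frame(scaffold = character(), start = numeric(), end = numeric(),
                 strand = character(), tx_id = character(),
                 gene_id = character()) else exons)

    scaf_len <- pos + 1000
    seqs <- character(0)
    for (sc in seq_len(n_scaffolds))
      seqs[sprintf("scaf%02d", sc)] <- .random_dna(scaf_len[sc], gc)
    contam_ids <- character(0)
    if (n_contaminant > 0) {
      contam_ids <- sprintf("ctg_bact%02d", seq_len(n_contaminant))
      for (id in contam_ids)
        seqs[id] <- .random_dna(contaminant_length, contaminant_gc)
    }
    coverage <- stats::setNames(rep(0, length(seqs)), names(seqs))
    normal <- setdiff(names(seqs), contam_ids)
    coverage[normal] <- round(stats::rgamma(length(normal), 4, scale = 10), 2)

    pairs <- if (length(truth_pairs)) do.call(rbind, truth_pairs) else
      data.frame(nested_gene = character(), host_gene = character())
    list(seqs = sequence_set(seqs, "nt"), ann = ann, coverage = coverage,
         truth = list(nested_genes = sort(pairs$nested_gene),
                      nested_pairs = pairs,
                      n_genes = n_genes,
                      single_exon_tx = sum(single) + nrow(pairs),
                      contaminant_scaffolds = contam_ids))
  })
}

#' Simulate a pair of genomes with known microsynteny structure
#'
#' Species A carries `n_genes` single-exon genes partitioned contiguously
#' over scaffolds; species B carries their orthologs in the same order
#' transformed by planted inversions and lineage-specific insertions,
#' optionally with a tandem gene-family array planted in A. The hit
#' table holds every true ortholog pair at top bitscore plus configurable
#' paralog and spurious noise hits at lower bitscore, so
#' [best_hit_per_query()] recovers exactly the planted ortholog map.
#'
#' @param seed Integer seed.
#' @param n_genes Ortholog pairs.
#' @param n_scaffolds_a,n_scaffolds_b Contiguous scaffold partitions.
#' @param inversions List of integer pairs `c(first, last)` (A-gene
#'   indices, 1-based, disjoint, each within one scaffold of both
#'   partitions) reversed in B; or an integer count of random disjoint
#'   segments of 5-8 genes.
#' @param insertion_rate Expected lineage-specific B insertions per
#'   ortholog gene.
#' @param paralog_rate Probability a query gains an extra lower-bitscore
#'   paralog hit.
#' @param spurious_rate Expected random noise hits per ortholog gene.
#' @param tandem Optional list `list(size =, interleave =)`: plants a
#'   tandem family array of `size` members on A scaffold 1, interleaved
#'   with ortholog genes at the given per-gap probability.
#' @return List with `ann_a`, `ann_b` ([annotation_set()]s), `hits`
#'   (`hit_table`) and `truth`: `anchors` (planted ortholog map),
#'   `segments` (expected collinear segments: `scaffold_a`, `scaffold_b`,
#'   A-index range, orientation, size), `inversions`, `family_map` and
#'   `tandem_members` when a tandem array was planted.
#' @export
simulate_ortholog_pair <- function(seed, n_genes = 100, n_scaffolds_a = 2,
                                   n_scaffolds_b = 2, inversions = list(),
                                   insertion_rate = 0, paralog_rate = 0,
                                   spurious_rate = 0, tandem = NULL) {
  .with_seed(seed, {
    chunk <- function(k) sort(rep_len(seq_len(k), n_genes))
    part_a <- chunk(n_scaffolds_a)
    part_b <- chunk(n_scaffolds_b)

    if (is.numeric(inversions) && length(inversions) == 1) {
      n_inv <- inversions
      inversions <- list()
      taken <- rep(FALSE, n_genes)
      tries <- 0
      while (length(inversions) < n_inv && tries < 200) {
        tries <- tries + 1
        len <- sample(5:8, 1)
        s <- sample(seq_len(max(1, n_genes - len + 1)), 1)
        seg <- s:(s + len - 1)
        if (any(taken[seg])) next
        if (length(unique(part_a[seg])) > 1 ||
            length(unique(part_b[seg])) > 1) next
        taken[seg] <- TRUE
        inversions[[length(inversions) + 1]] <- c(s, s + len - 1)
      }
    }
    if (length(inversions)) {
      segs <- do.call(rbind, lapply(inversions, function(v) sort(v)))
      segs <- segs[order(segs[, 1]), , drop = FALSE]
      if (any(segs[-1, 1] <= segs[-nrow(segs), 2]))
        stop("inversion segments overlap")
      for (i in seq_len(nrow(segs))) {
        seg <- segs[i, 1]:segs[i, 2]
        if (length(unique(part_a[seg])) > 1 ||
            length(unique(part_b[seg])) > 1)
          stop("inversion segment crosses a scaffold boundary")
      }
      inversions <- lapply(seq_len(nrow(segs)), function(i) segs[i, ])
    }

    ga <- sprintf("ga%04d", seq_len(n_genes))
    gb <- sprintf("gb%04d", seq_len(n_genes))
    inverted <- rep(FALSE, n_genes)
    order_b_idx <- seq_len(n_genes)
    for (seg in inversions) {
      idx <- seg[1]:seg[2]
      order_b_idx[idx] <- rev(idx)
      inverted[idx] <- TRUE
    }

    # species A order with optional tandem array on scaffold 1
    a_ids <- ga
    a_scafs <- sprintf("sa%02d", part_a)
    family_map <- NULL; tandem_members <- NULL
    if (!is.null(tandem)) {
      size <- tandem$size
      interleave <- if (is.null(tandem$interleave)) 0 else tandem$interleave
      tandem_members <- sprintf("tand%03d", seq_len(size))
      first_scaf <- sum(part_a == 1)
      anchor <- sample(seq_len(max(1, first_scaf - size)), 1)
      new_ids <- character(0); new_scafs <- character(0)
      stream <- anchor  # next A gene index to emit
      emit <- function(n) {
        if (n > 0) {
          new_ids <<- c(new_ids, a_ids[stream:(stream + n - 1)])
          new_scafs <<- c(new_scafs, a_scafs[stream:(stream + n - 1)])
          stream <<- stream + n
        }
      }
      new_ids <- a_ids[seq_len(anchor - 1)]
      new_scafs <- a_scafs[seq_len(anchor - 1)]
      for (i in seq_len(size)) {
        new_ids <- c(new_ids, tandem_members[i])
        new_scafs <- c(new_scafs, "sa01")
        if (i < size && stats::runif(1) < interleave) emit(1)
      }
      emit(n_genes - stream + 1)
      a_ids <- new_ids; a_scafs <- new_scafs
      family_map <- stats::setNames(rep("famT", size), tandem_members)
    }

    # species B order: per scaffold, orthologs after inversion, plus
    # lineage-specific insertions
    b_ids <- gb[order_b_idx]
    b_scafs <- sprintf("sb%02d", part_b)
    if (insertion_rate > 0) {
      n_ins <- stats::rbinom(1, n_genes, min(1, insertion_rate))
      if (n_ins > 0) {
        at <- sort(sample(seq_along(b_ids), n_ins))
        ins_ids <- sprintf("bnov%03d", seq_len(n_ins))
        out_ids <- character(0); out_scafs <- character(0); prev <- 0
        for (j in seq_len(n_ins)) {
          out_ids <- c(out_ids, b_ids[seq_len(at[j])[seq_len(at[j]) > prev]],
                       ins_ids[j])
          out_scafs <- c(out_scafs,
                         b_scafs[seq_len(at[j])[seq_len(at[j]) > prev]],
                         b_scafs[at[j]])
          prev <- at[j]
        }
        if (prev < length(b_ids)) {
          out_ids <- c(out_ids, b_ids[(prev + 1):length(b_ids)])
          out_scafs <- c(out_scafs, b_scafs[(prev + 1):length(b_scafs)])
        }
        b_ids <- out_ids; b_scafs <- out_scafs
      }
    }

    mk_ann <- function(ids, scafs) {
      ord <- stats::ave(seq_along(ids), scafs, FUN = seq_along) - 1
      start <- ord * 2000 + 100
      annotation_set(data.frame(scaffold = scafs, start = start,
                                end = start + 1000, strand = "+",
                                tx_id = paste0(ids, ".t1"), gene_id = ids))
    }
    ann_a <- mk_ann(a_ids, a_scafs)
    ann_b <- mk_ann(b_ids, b_scafs)

    mk_hit <- function(q, s, bitscore, pident) {
      n <- length(q)
      data.frame(query = q, subject = s, pident = round(pident, 1),
                 length = rep(300L, n), mismatch = rep(10L, n),
                 gapopen = rep(1L, n), qstart = rep(1L, n),
                 qend = rep(300L, n), sstart = rep(1L, n),
                 send = rep(300L, n),
                 evalue = signif(10^(-stats::runif(n, 50, 150)), 3),
                 bitscore = round(bitscore, 1))
    }
    hits <- mk_hit(ga, gb, stats::runif(n_genes, 300, 500),
                   stats::runif(n_genes, 60, 95))
    if (paralog_rate > 0) {
      par_q <- which(stats::runif(n_genes) < paralog_rate)
      if (length(par_q)) {
        par_s <- vapply(par_q, function(i)
          sample(setdiff(seq_len(n_genes), i), 1), 0L)
        hits <- rbind(hits, mk_hit(ga[par_q], gb[par_s],
                                   stats::runif(length(par_q), 100, 250),
                                   stats::runif(length(par_q), 40, 60)))
      }
    }
    if (spurious_rate > 0) {
      n_spur <- stats::rbinom(1, n_genes, min(1, spurious_rate))
      if (n_spur > 0)
        hits <- rbind(hits, mk_hit(ga[sample(n_genes, n_spur, TRUE)],
                                   gb[sample(n_genes, n_spur, TRUE)],
                                   stats::runif(n_spur, 50, 150),
                                   stats::runif(n_spur, 30, 50)))
    }

    # expected collinear segments: break at scaffold boundaries (either
    # species) and at inversion boundaries
    breaks <- sort(unique(c(
      0, n_genes, cumsum(table(part_a)), cumsum(table(part_b)),
      unlist(lapply(inversions, function(v) c(v[1] - 1, v[2]))))))
    seg_lo <- breaks[-length(breaks)] + 1
    seg_hi <- breaks[-1]
    segments <- data.frame(
      scaffold_a = sprintf("sa%02d", part_a[seg_lo]),
      scaffold_b = sprintf("sb%02d", part_b[seg_lo]),
      a_first = seg_lo, a_last = seg_hi,
      orientation = ifelse(inverted[seg_lo], "-", "+"),
      size = seg_hi - seg_lo + 1)
    rownames(segments) <- NULL

    list(ann_a = ann_a, ann_b = ann_b, hits = hit_table(hits),
         truth = list(anchors = data.frame(gene_a = ga, gene_b = gb),
                      segments = segments, inversions = inversions,
                      family_map = family_map,
                      tandem_members = tandem_members))
  })
}
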