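# Independent oracles and small random-input builders for the test suite.
# Each oracle deliberately re-derives its quantity by the most direct
# brute-force route, sharing no code with the package implementation.

# all-pairs containment scan: gene nested iff its span fits inside one
# intron of another gene's transcript on the same scaffold
oracle_nested_genes <- function(ann) {
  genes <- ann$genes
  introns <- ann_introns(ann)
  nested <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    for (j in seq_len(nrow(introns))) {
      it <- introns[j, ]
      if (it$scaffold == g$scaffold && it$gene_id != g$gene_id &&
          it$start <= g$start && g$end <= it$end) {
        nested <- c(nested, g$gene_id)
        break
      }
    }
  }
  sort(unique(nested))
}

# upper hypergeometric tail by explicit log-space enumeration
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  sum(exp(logp[x >= a]))
}

# run scan for adjacency chains (max_gap = 0): maximal runs where the
# a-ordinal advances by 1 and the b-ordinal steps by a constant +1 or -1
oracle_adjacent_runs <- function(a_ord, b_ord, min_block = 3) {
  o <- order(a_ord)
  a <- a_ord[o]; b <- b_ord[o]
  runs <- list(); start <- 1; dir <- 0
  flush <- function(from, to, dir) {
    if (to - from + 1 >= min_block)
      runs[[length(runs) + 1]] <<- list(size = to - from + 1,
                                        orientation = if (dir < 0) "-" else "+")
  }
  i <- 2
  while (i <= length(a)) {
    da <- a[i] - a[i - 1]; db <- b[i] - b[i - 1]
    ok <- da == 1 && abs(db) == 1 && (dir == 0 || db == dir)
    if (ok) {
      if (dir == 0) dir <- db
    } else {
      flush(start, i - 1, dir)
      start <- i; dir <- 0
    }
    i <- i + 1
  }
  flush(start, length(a), dir)
  runs
}

# weighted rank aggregation computed the long way, metric by metric
oracle_rank_order <- function(table, scheme) {
  ids <- table$assembly
  score <- rep(0, nrow(table))
  for (i in seq_len(nrow(scheme))) {
    x <- table[[scheme$metric[i]]]
    r <- if (scheme$direction[i] == "higher_better")
      rank(-x, ties.method = "average") else rank(x, ties.method = "average")
    score <- score + scheme$weight[i] * r
  }
  ids[order(score, ids)]
}

# random annotation with unconstrained gene overlaps, to stress nested
# detection with accidental containments and shared introns
random_annotation <- function(seed, n_genes = 40, n_scaffolds = 2) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_genes)) {
    scaf <- sprintf("s%d", sample(n_scaffolds, 1))
    start <- sample(0:3000, 1)
    k <- sample(1:4, 1)
    exon_len <- sample(10:200, k, replace = TRUE)
    intron_len <- if (k > 1) sample(5:400, k - 1, replace = TRUE) else integer(0)
    starts <- start + cumsum(c(0, (exon_len + c(intron_len, 0))[-k]))
    gene <- sprintf("g%03d", i)
    rows[[i]] <- data.frame(scaffold = scaf, start = starts,
                            end = starts + exon_len,
                            strand = sample(c("+", "-"), 1),
                            tx_id = paste0(gene, ".t1"), gene_id = gene)
  }
  annotation_set(do.call(rbind, rows))
}

# tiny literal GFF3 fixture written on the fly
write_mini_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "s1\ttest\tgene\t100\t900\t.\t+\t.\tID=geneA",
    "s1\ttest\tmRNA\t100\t900\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "s1\ttest\texon\t100\t200\t.\t+\t.\tParent=geneA.t1",
    "s1\ttest\texon\t800\t900\t.\t+\t.\tParent=geneA.t1",
    "s1\ttest\tgene\t300\t700\t.\t-\t.\tID=geneB",
    "s1\ttest\tmRNA\t300\t700\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "s1\ttest\texon\t300\t700\t.\t-\t.\tParent=geneB.t1"), path)
  path
}
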