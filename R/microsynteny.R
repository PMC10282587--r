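#' Remove high-copy gene families from a hit table
#'
#' Large gene families and transposons with parallel expansions in both
#' genomes generate dense spurious matches; any protein (query or subject
#' side) participating in more than `max_hits` retained hits is removed
#' together with all of its hits. Removal can drop other proteins below
#' the threshold, so the rule is applied iteratively to a fixed point: in
#' the returned table no protein exceeds `max_hits`.
#'
#' @param hits A `hit_table`.
#' @param max_hits Maximum allowed hits per protein (default 50).
#' @return Filtered `hit_table`.
#' @export
filter_high_copy_hits <- function(hits, max_hits = 50) {
  if (max_hits < 1) stop("max_hits must be >= 1")
  hits <- hit_table(as.data.frame(hits))
  repeat {
    if (!nrow(hits)) break
    counts <- table(c(hits$query, hits$subject))
    over <- names(counts)[counts > max_hits]
    if (!length(over)) break
    hits <- hits[!(hits$query %in% over | hits$subject %in% over), ,
                 drop = FALSE]
  }
  hit_table(as.data.frame(hits))
}

#' Per-scaffold gene order
#'
#' @param ann An [annotation_set()].
#' @return Object of class `gene_order`: list with `index` (data.frame
#'   `gene_id`, `scaffold`, `ordinal`; ordinals start at 0 per scaffold,
#'   genes sorted by span start, ties broken by id) and `order` (named
#'   list scaffold -> gene id vector).
#' @export
build_gene_order <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  g <- ann$genes[order(ann$genes$scaffold, ann$genes$start,
                       ann$genes$gene_id), , drop = FALSE]
  ord <- stats::ave(seq_len(nrow(g)), g$scaffold, FUN = seq_along) - 1L
  index <- data.frame(gene_id = g$gene_id, scaffold = g$scaffold,
                      ordinal = as.integer(ord))
  rownames(index) <- NULL
  structure(list(index = index,
                 order = split(index$gene_id, index$scaffold)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("gene_order:", nrow(x$index), "genes on", length(x$order),
      "scaffold(s)\n")
  invisible(x)
}

#' Reduce a hit table to the best hit per query
#'
#' Keeps, per query, the hit with the highest bitscore; ties go to the
#' smaller evalue, then the lexicographically smallest subject id. The
#' result is the "unidirectional" anchor set for block detection.
#'
#' @param hits A `hit_table`.
#' @return `hit_table` with at most one row per query.
#' @export
best_hit_per_query <- function(hits) {
  df <- as.data.frame(hits)
  if (!nrow(df)) return(hit_table(NULL))
  o <- order(df$query, -df$bitscore, df$evalue, df$subject)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df$query), , drop = FALSE]
  hit_table(df)
}

.hit_ordinals <- function(hits, order_a, order_b) {
  ia <- order_a$index; ib <- order_b$index
  qa <- match(hits$query, ia$gene_id)
  sb <- match(hits$subject, ib$gene_id)
  if (anyNA(qa))
    stop("query id(s) absent from gene order: ",
         paste(utils::head(hits$query[is.na(qa)], 10), collapse = ", "))
  if (anyNA(sb))
    stop("subject id(s) absent from gene order: ",
         paste(utils::head(hits$subject[is.na(sb)], 10), collapse = ", "))
  data.frame(query = hits$query, subject = hits$subject,
             scaffold_a = ia$scaffold[qa], ordinal_a = ia$ordinal[qa],
             scaffold_b = ib$scaffold[sb], ordinal_b = ib$ordinal[sb],
             bitscore = hits$bitscore)
}

#' Detect collinear microsynteny blocks
#'
#' Within each scaffold pair, anchors (best-hit gene pairs) sorted by
#' a-side ordinal are chained greedily left to right. An anchor extends
#' the open chain when at most `max_gap` genes are skipped on the a side
#' and its b-side ordinal continues the chain's direction, again skipping
#' at most `max_gap` genes. The second anchor of a chain sets the
#' direction. Chains of at least `min_block` anchors are reported; each
#' anchor belongs to at most one block.
#'
#' @param anchor_hits A `hit_table`, already reduced to at most one
#'   partner per query (see [best_hit_per_query()]).
#' @param order_a,order_b [build_gene_order()] results for the two
#'   annotations.
#' @param min_block Minimum anchors per reported block (default 3).
#' @param max_gap Maximum skipped genes between consecutive anchors on
#'   either side (default 5).
#' @return data.frame of class `synteny_blocks`: one row per block with
#'   `block_id`, `scaffold_a`, `scaffold_b`, `orientation` (`+`/`-`),
#'   `size`, and an `anchors` list-column of data.frames (`gene_a`,
#'   `gene_b`, `ordinal_a`, `ordinal_b`).
#' @export
detect_synteny_blocks <- function(anchor_hits, order_a, order_b,
                                  min_block = 3, max_gap = 5) {
  if (anyDuplicated(anchor_hits$query))
    stop("anchor_hits has multiple hits per query; apply best_hit_per_query")
  an <- .hit_ordinals(anchor_hits, order_a, order_b)
  blocks <- list()
  if (nrow(an)) {
    an$pair <- paste(an$scaffold_a, an$scaffold_b, sep = "\r")
    for (pr in split(an, an$pair)) {
      pr <- pr[order(pr$ordinal_a, pr$ordinal_b), , drop = FALSE]
      chain <- list(); dir <- 0L
      flush <- function() {
        if (length(chain) >= min_block) {
          df <- do.call(rbind, chain)
          blocks[[length(blocks) + 1]] <<- list(
            scaffold_a = df$scaffold_a[1], scaffold_b = df$scaffold_b[1],
            orientation = if (dir < 0) "-" else "+", anchors = df)
        }
      }
      for (i in seq_len(nrow(pr))) {
        row <- pr[i, ]
        if (!length(chain)) { chain <- list(row); dir <- 0L; next }
        last <- chain[[length(chain)]]
        da <- row$ordinal_a - last$ordinal_a
        db <- row$ordinal_b - last$ordinal_b
        ok <- da >= 1 && da <= max_gap + 1 &&
          ((dir == 0L && abs(db) >= 1 && abs(db) <= max_gap + 1) ||
           (dir > 0L && db >= 1 && db <= max_gap + 1) ||
           (dir < 0L && db <= -1 && db >= -(max_gap + 1)))
        if (ok) {
          if (dir == 0L) dir <- sign(db)
          chain[[length(chain) + 1]] <- row
        } else {
          flush()
          chain <- list(row); dir <- 0L
        }
      }
      flush()
    }
  }
  out <- data.frame(
    block_id = seq_along(blocks),
    scaffold_a = vapply(blocks, `[[`, "", "scaffold_a"),
    scaffold_b = vapply(blocks, `[[`, "", "scaffold_b"),
    orientation = vapply(blocks, `[[`, "", "orientation"),
    size = vapply(blocks, function(b) nrow(b$anchors), 0L))
  out$anchors <- lapply(blocks, function(b) {
    a <- b$anchors[c("query", "subject", "ordinal_a", "ordinal_b")]
    names(a)[1:2] <- c("gene_a", "gene_b")
    rownames(a) <- NULL
    a
  })
  if (nrow(out)) {
    o <- order(out$scaffold_a, out$scaffold_b,
               vapply(out$anchors, function(a) a$ordinal_a[1], 0))
    out <- out[o, , drop = FALSE]
    out$block_id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  class(out) <- c("synteny_blocks", "data.frame")
  out
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat("synteny_blocks:", nrow(x), "blocks,",
      if (nrow(x)) sum(x$size) else 0, "anchors\n")
  if (nrow(x))
    print.data.frame(utils::head(
      x[c("block_id", "scaffold_a", "scaffold_b", "orientation", "size")], 10))
  invisible(x)
}

#' Fisher's exact enrichment test per scaffold pair
#'
#' For every scaffold pair with at least one hit, a 2x2 table is built
#' from the retained hits: matches between the two scaffolds (`a`),
#' matches of the a-side scaffold elsewhere (`b`), matches to the b-side
#' scaffold from elsewhere (`c`), and all remaining matches (`d`). A
#' one-sided (enrichment) Fisher's exact test is computed per pair and
#' Benjamini-Hochberg adjusted across all tested pairs.
#'
#' @param hits A `hit_table`.
#' @param order_a,order_b [build_gene_order()] results used to resolve
#'   hit ids to scaffolds.
#' @return data.frame of class `pair_tests`: `scaffold_a`, `scaffold_b`,
#'   `a`, `b`, `c`, `d`, `p`, `p_adj`, sorted by `p`.
#' @export
scaffold_pair_significance <- function(hits, order_a, order_b) {
  an <- .hit_ordinals(hits, order_a, order_b)
  if (!nrow(an)) {
    out <- data.frame(scaffold_a = character(), scaffold_b = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p = numeric(), p_adj = numeric())
    class(out) <- c("pair_tests", "data.frame")
    return(out)
  }
  n <- nrow(an)
  tab <- table(an$scaffold_a, an$scaffold_b)
  idx <- which(tab > 0, arr.ind = TRUE)
  a <- as.integer(tab[idx])
  row_tot <- rowSums(tab)[idx[, 1]]
  col_tot <- colSums(tab)[idx[, 2]]
  b <- as.integer(row_tot - a)
  cc <- as.integer(col_tot - a)
  d <- as.integer(n - a - b - cc)
  p <- vapply(seq_along(a), function(i)
    pair_fisher_p(a[i], b[i], cc[i], d[i]), 0)
  out <- data.frame(scaffold_a = rownames(tab)[idx[, 1]],
                    scaffold_b = colnames(tab)[idx[, 2]],
                    a = a, b = b, c = cc, d = d,
                    p = p, p_adj = stats::p.adjust(p, method = "BH"))
  out <- out[order(out$p, out$scaffold_a, out$scaffold_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_tests", "data.frame")
  out
}

#' One-sided Fisher's exact p for a 2x2 enrichment table
#'
#' Probability, under fixed margins, of observing at least `a` matches
#' between the scaffold pair: the upper hypergeometric tail.
#'
#' @param a,b,c,d The 2x2 cell counts (pair hits, a-side elsewhere,
#'   b-side from elsewhere, rest).
#' @return The one-sided (greater) p-value.
#' @export
pair_fisher_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2),
                     alternative = "greater")$p.value
}

#' Export a synteny dot plot table
#'
#' One row per hit with both gene ordinals, the numeric skeleton of the
#' classic macro/microsynteny dot plot (diagonals = conserved order).
#'
#' @param hits A `hit_table`.
#' @param order_a,order_b [build_gene_order()] results.
#' @param path Output TSV path.
#' @return The exported data.frame (`scaffold_a`, `ordinal_a`,
#'   `scaffold_b`, `ordinal_b`, `bitscore`), invisibly; deterministic row
#'   order.
#' @export
export_dotplot <- function(hits, order_a, order_b, path) {
  an <- .hit_ordinals(hits, order_a, order_b)
  out <- an[c("scaffold_a", "ordinal_a", "scaffold_b", "ordinal_b",
              "bitscore")]
  out <- out[order(out$scaffold_a, out$ordinal_a, out$scaffold_b,
                   out$ordinal_b), , drop = FALSE]
  rownames(out) <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Classify genes as syntenic or non-syntenic
#'
#' @param blocks A `synteny_blocks` result.
#' @param ann The [annotation_set()] whose genes are classified (either
#'   side of the comparison).
#' @return Named character vector gene id -> `"syntenic"` /
#'   `"non_syntenic"`; a gene is syntenic when it anchors at least one
#'   block.
#' @export
classify_syntenic_genes <- function(blocks, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  anchored <- unique(unlist(lapply(blocks$anchors, function(a)
    c(a$gene_a, a$gene_b))))
  ids <- ann$genes$gene_id
  stats::setNames(ifelse(ids %in% anchored, "syntenic", "non_syntenic"), ids)
}

#' Detect tandem gene-family clusters
#'
#' Scans each scaffold's gene order for runs of same-family genes.
#' Consecutive family members separated by at most `max_interleave`
#' non-member genes are merged into one cluster, so tandem arrays
#' interleaved with unrelated genes are still recovered.
#'
#' @param ann An [annotation_set()].
#' @param family_map Named character vector gene id -> family id; genes
#'   absent from it never cluster.
#' @param min_cluster Minimum members per reported cluster (default 3).
#' @param max_interleave Maximum interleaved non-members between
#'   consecutive members (default 3).
#' @return data.frame of class `tandem_clusters`: `scaffold`, `family`,
#'   `n_members`, `ordinal_start`, `ordinal_end`, `interleaved_count`,
#'   plus a `members` list-column of gene id vectors in scaffold order.
#' @export
detect_tandem_clusters <- function(ann, family_map, min_cluster = 3,
                                   max_interleave = 3) {
  ord <- build_gene_order(ann)$index
  ord$family <- unname(family_map[ord$gene_id])
  rows <- list()
  for (scaf_df in split(ord, ord$scaffold)) {
    members <- scaf_df[!is.na(scaf_df$family), , drop = FALSE]
    for (fam_df in split(members, members$family)) {
      fam_df <- fam_df[order(fam_df$ordinal), , drop = FALSE]
      gaps <- diff(fam_df$ordinal)
      grp <- cumsum(c(0, gaps > max_interleave + 1))
      for (cl in split(fam_df, grp)) {
        if (nrow(cl) < min_cluster) next
        rows[[length(rows) + 1]] <- data.frame(
          scaffold = cl$scaffold[1], family = cl$family[1],
          n_members = nrow(cl),
          ordinal_start = min(cl$ordinal), ordinal_end = max(cl$ordinal),
          interleaved_count =
            (max(cl$ordinal) - min(cl$ordinal) + 1) - nrow(cl),
          members = I(list(cl$gene_id)))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(), family = character(),
               n_members = integer(), ordinal_start = integer(),
               ordinal_end = integer(), interleaved_count = integer(),
               members = I(list()))
  out <- out[order(out$scaffold, out$ordinal_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tandem_clusters", "data.frame")
  out
}
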