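single_exon_ann <- function(ids, scafs, starts) {
  annotation_set(data.frame(scaffold = scafs, start = starts,
                            end = starts + 100, strand = "+",
                            tx_id = paste0(ids, ".t"), gene_id = ids))
}
mk_hits <- function(q, s, bits = 200, ev = 1e-50)
  hit_table(data.frame(query = q, subject = s, evalue = ev, bitscore = bits))

test_that("gene order assigns per-scaffold ordinals with id tie-break", {
  ann <- single_exon_ann(c("a", "b", "c", "d", "e"),
                         c("s1", "s1", "s1", "s2", "s2"),
                         c(10, 5, 20, 7, 7))
  ord <- build_gene_order(ann)
  ix <- ord$index
  expect_equal(ix$ordinal[match(c("b", "a", "c"), ix$gene_id)], c(0, 1, 2))
  # equal starts on s2: lexicographic by id
  expect_equal(ix$ordinal[match(c("d", "e"), ix$gene_id)], c(0, 1))
})

test_that("high-copy filtering reaches a fixed point", {
  # one promiscuous query with 51 subjects, plus clean pairs
  noisy <- mk_hits(rep("q_bad", 51), sprintf("t%03d", 1:51))
  clean <- mk_hits(c("q1", "q2"), c("u1", "u2"))
  out <- filter_high_copy_hits(hit_table(rbind(noisy, clean)), max_hits = 50)
  expect_equal(sort(out$query), c("q1", "q2"))

  # under the threshold: unchanged
  expect_equal(nrow(filter_high_copy_hits(clean, 50)), 2)

  # cascade: removing hub drops its partner below min representation;
  # fixed point property: no retained protein exceeds max_hits
  star <- mk_hits(rep("hub", 6), sprintf("leaf%d", 1:6))
  extra <- mk_hits(c("leaf1", "leaf1", "x"), c("y1", "y2", "leaf2"))
  res <- filter_high_copy_hits(hit_table(rbind(star, extra)), max_hits = 5)
  counts <- table(c(res$query, res$subject))
  expect_true(all(counts <= 5))
  # brute-force fixed point agrees
  brute <- rbind(star, extra)
  repeat {
    cnt <- table(c(brute$query, brute$subject))
    bad <- names(cnt)[cnt > 5]
    if (!length(bad)) break
    brute <- brute[!(brute$query %in% bad | brute$subject %in% bad), ]
  }
  expect_equal(as.data.frame(res), as.data.frame(hit_table(brute)))
  expect_error(filter_high_copy_hits(clean, 0), "max_hits")
})

test_that("best hit per query follows bitscore, evalue, subject tie-breaks", {
  h <- hit_table(data.frame(query = c("q", "q", "q", "r"),
                            subject = c("s1", "s2", "s3", "s9"),
                            evalue = c(1e-50, 1e-60, 1e-60, 1e-10),
                            bitscore = c(150, 200, 200, 90)))
  best <- best_hit_per_query(h)
  expect_equal(nrow(best), 2)
  expect_equal(best$subject[best$query == "q"], "s2")  # tie -> smaller evalue,
  # then lexicographic subject (s2 < s3)
})

test_that("identity and inverted orders chain into the expected blocks", {
  ids_a <- sprintf("a%02d", 1:10)
  ids_b <- sprintf("b%02d", 1:10)
  oa <- build_gene_order(single_exon_ann(ids_a, "sa", (1:10) * 1000))
  # identity: one + block of 10
  ob <- build_gene_order(single_exon_ann(ids_b, "sb", (1:10) * 1000))
  bl <- detect_synteny_blocks(mk_hits(ids_a, ids_b), oa, ob, 3, 0)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$size, 10)
  expect_equal(bl$orientation, "+")

  # genes 4-6 reversed in B, max_gap 0: 3 blocks (+,-,+)
  perm <- c(1:3, 6:4, 7:10)
  ob2 <- build_gene_order(single_exon_ann(ids_b[perm], "sb", (1:10) * 1000))
  bl2 <- detect_synteny_blocks(mk_hits(ids_a, ids_b), oa, ob2, 3, 0)
  expect_equal(bl2$size, c(3, 3, 4))
  expect_equal(bl2$orientation, c("+", "-", "+"))

  expect_error(detect_synteny_blocks(mk_hits(c("a01", "a01"), c("b01", "b02")),
                                     oa, ob), "best_hit_per_query")
})

test_that("chaining equals the adjacency-run oracle on random permutations", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 100
    perm <- sample(n)
    ids_a <- sprintf("a%03d", 1:n)
    ids_b <- sprintf("b%03d", 1:n)
    oa <- build_gene_order(single_exon_ann(ids_a, "sa", (1:n) * 10))
    ob <- build_gene_order(single_exon_ann(ids_b[order(perm)], "sb",
                                           (1:n) * 10))
    bl <- detect_synteny_blocks(mk_hits(ids_a, ids_b), oa, ob, 3, 0)
    runs <- oracle_adjacent_runs(0:(n - 1), perm - 1, 3)
    expect_equal(nrow(bl), length(runs), info = paste("seed", seed))
    if (length(runs)) {
      expect_equal(bl$size, vapply(runs, `[[`, 0, "size"))
      expect_equal(bl$orientation, vapply(runs, `[[`, "", "orientation"))
    }
    # every anchor in at most one block
    all_anchors <- unlist(lapply(bl$anchors, function(a) a$gene_a))
    expect_false(any(duplicated(all_anchors)))
  }
})

test_that("reversing one scaffold flips every block orientation", {
  sim <- simulate_ortholog_pair(13, n_genes = 60, n_scaffolds_a = 1,
                                n_scaffolds_b = 1,
                                inversions = list(c(20, 26)))
  oa <- build_gene_order(sim$ann_a)
  ob <- build_gene_order(sim$ann_b)
  anch <- best_hit_per_query(sim$hits)
  bl <- detect_synteny_blocks(anch, oa, ob, 3, 0)

  rev_ex <- sim$ann_b$exons
  rev_ex$start2 <- max(rev_ex$end) - rev_ex$end
  rev_ex$end <- max(rev_ex$end) - rev_ex$start
  rev_ex$start <- rev_ex$start2
  rev_ex$start2 <- NULL
  ob_rev <- build_gene_order(annotation_set(rev_ex))
  bl_rev <- detect_synteny_blocks(anch, oa, ob_rev, 3, 0)
  expect_equal(nrow(bl_rev), nrow(bl))
  expect_equal(sort(bl_rev$size), sort(bl$size))
  expect_equal(sum(bl_rev$orientation == "+"), sum(bl$orientation == "-"))
})

test_that("Fisher 2x2 machinery matches the closed case and adjusts with BH", {
  expect_equal(pair_fisher_p(2, 0, 0, 2), 1 / 6, tolerance = 1e-12)
  expect_equal(pair_fisher_p(0, 5, 7, 11), 1)

  # monotone: with fixed margins, larger a gives smaller (or equal) p
  p_prev <- 1
  for (a in 0:5) {
    p <- pair_fisher_p(a, 5 - a, 5 - a, 5 + a)
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }

  sim <- simulate_ortholog_pair(5, n_genes = 60, spurious_rate = 0.2)
  oa <- build_gene_order(sim$ann_a); ob <- build_gene_order(sim$ann_b)
  pt <- scaffold_pair_significance(sim$hits, oa, ob)
  expect_true(all(pt$a + pt$b + pt$c + pt$d == nrow(sim$hits)))
  expect_true(all(pt$p_adj >= pt$p - 1e-15))
  expect_equal(pt$p_adj, p.adjust(pt$p, "BH"))
})

test_that("dot plot export writes deterministic ordinal rows", {
  sim <- simulate_ortholog_pair(9, n_genes = 30,
                                inversions = list(c(4, 10)))
  oa <- build_gene_order(sim$ann_a); ob <- build_gene_order(sim$ann_b)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- export_dotplot(sim$hits, oa, ob, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(sim$hits))
  # planted inversion appears as an anti-diagonal segment
  seg <- out[out$scaffold_a == "sa01" & out$ordinal_a %in% 3:9, ]
  expect_true(all(diff(seg$ordinal_b[order(seg$ordinal_a)]) == -1))

  empty <- export_dotplot(hit_table(NULL), oa, ob, path)
  expect_equal(nrow(read.delim(path)), 0)
})

test_that("genes are classified syntenic iff they anchor a block", {
  sim <- simulate_ortholog_pair(2, n_genes = 10)
  oa <- build_gene_order(sim$ann_a); ob <- build_gene_order(sim$ann_b)
  no_blocks <- detect_synteny_blocks(hit_table(NULL), oa, ob)
  cls0 <- classify_syntenic_genes(no_blocks, sim$ann_a)
  expect_true(all(cls0 == "non_syntenic"))

  bl <- detect_synteny_blocks(best_hit_per_query(sim$hits), oa, ob, 3, 0)
  cls <- classify_syntenic_genes(bl, sim$ann_a)
  expect_equal(sum(cls == "syntenic"), 10)
})

test_that("tandem clusters merge across limited interleaving", {
  ann <- single_exon_ann(sprintf("g%02d", 1:12), "s1", (1:12) * 500)
  fam <- setNames(rep("F", 3), c("g01", "g02", "g03"))
  tc <- detect_tandem_clusters(ann, fam)
  expect_equal(nrow(tc), 1)
  expect_equal(tc$n_members, 3)
  expect_equal(tc$interleaved_count, 0)

  # members at ordinals 0,2,4 with max_interleave 1: one cluster, 2 interleaved
  fam2 <- setNames(rep("F", 3), c("g01", "g03", "g05"))
  tc2 <- detect_tandem_clusters(ann, fam2, max_interleave = 1)
  expect_equal(tc2$n_members, 3)
  expect_equal(tc2$interleaved_count, 2)

  # members too far apart: no cluster
  fam3 <- setNames(rep("F", 2), c("g01", "g11"))
  expect_equal(nrow(detect_tandem_clusters(ann, fam3)), 0)

  # simulated tandem array is recovered with its members
  sim <- simulate_ortholog_pair(31, n_genes = 80,
                                tandem = list(size = 12, interleave = 0.4))
  tc4 <- detect_tandem_clusters(sim$ann_a, sim$truth$family_map,
                                min_cluster = 3, max_interleave = 3)
  expect_equal(nrow(tc4), 1)
  expect_equal(sort(tc4$members[[1]]), sort(sim$truth$tandem_members))
})
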