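make_ann <- function(...) annotation_set(rbind(...))
exon_row <- function(gene, start, end, scaf = "s1", strand = "+",
                     tx = paste0(gene, ".t1"))
  data.frame(scaffold = scaf, start = start, end = end, strand = strand,
             tx_id = tx, gene_id = gene)

test_that("a gene inside a single host intron is nested; edge cases are not", {
  ann <- make_ann(exon_row("H", c(100, 800), c(200, 900)),
                  exon_row("G", 300, 700))
  rep <- detect_nested_genes(ann)
  expect_equal(rep$nested_genes, "G")
  expect_equal(rep$pairs$host_gene, "H")
  expect_equal(rep$pairs$intron_start, 200)
  expect_equal(rep$pairs$intron_end, 800)
  expect_equal(rep$nested_fraction, 0.5)

  # single gene: nothing to nest in
  solo <- make_ann(exon_row("A", 0, 100))
  expect_equal(detect_nested_genes(solo)$nested_gene_count, 0)

  # gene overlapping a host exon spans two introns: not nested
  ann2 <- make_ann(exon_row("H", c(0, 300, 600), c(100, 400, 700)),
                   exon_row("G", 150, 500))
  expect_equal(detect_nested_genes(ann2)$nested_gene_count, 0)

  # different scaffold: not nested
  ann3 <- make_ann(exon_row("H", c(100, 800), c(200, 900)),
                   exon_row("G", 300, 700, scaf = "s2"))
  expect_equal(detect_nested_genes(ann3)$nested_gene_count, 0)
})

test_that("nested detection is strand-agnostic unless asked otherwise", {
  host <- exon_row("H", c(100, 800), c(200, 900), strand = "+")
  same <- make_ann(host, exon_row("G", 300, 700, strand = "+"))
  opp <- make_ann(host, exon_row("G", 300, 700, strand = "-"))
  expect_equal(detect_nested_genes(same)$nested_gene_count, 1)
  expect_equal(detect_nested_genes(opp)$nested_gene_count, 1)
  expect_equal(detect_nested_genes(same,
    require_opposite_strand = TRUE)$nested_gene_count, 0)
  expect_equal(detect_nested_genes(opp,
    require_opposite_strand = TRUE)$nested_gene_count, 1)
})

test_that("nested detection matches the brute-force oracle on random annotations", {
  for (seed in 1:25) {
    ann <- random_annotation(seed, n_genes = sample(10:60, 1))
    expect_equal(detect_nested_genes(ann)$nested_genes,
                 oracle_nested_genes(ann), info = paste("seed", seed))
  }
})

test_that("nested count survives scaffold renaming and grows monotonically", {
  ann <- random_annotation(99, n_genes = 50)
  renamed <- ann$exons
  renamed$scaffold <- paste0("chr_", renamed$scaffold)
  expect_equal(detect_nested_genes(annotation_set(renamed))$nested_gene_count,
               detect_nested_genes(ann)$nested_gene_count)

  # drop a new gene wholly inside an existing intron: count +>= 1
  introns <- ann_introns(ann)
  wide <- introns[which.max(introns$end - introns$start), ]
  stopifnot(wide$end - wide$start > 10)
  extra <- rbind(ann$exons,
                 exon_row("extra", wide$start + 2, wide$end - 2,
                          scaf = wide$scaffold))
  n0 <- detect_nested_genes(ann)$nested_gene_count
  expect_gte(detect_nested_genes(annotation_set(extra))$nested_gene_count,
             n0 + 1)
})

test_that("bulk stats count unions, single-exon transcripts and introns", {
  one <- make_ann(exon_row("A", 0, 500))
  st <- genome_bulk_stats(one)
  expect_equal(st$gene_count, 1)
  expect_equal(st$single_exon_transcript_count, 1)
  expect_equal(st$total_exonic_bp, 500)
  expect_equal(st$intron_count, 0)
  expect_true(is.na(st$mean_intron_length))

  # overlapping isoform exons count once in the gene's exonic bp
  iso <- make_ann(exon_row("A", 0, 100, tx = "A.t1"),
                  exon_row("A", 50, 150, tx = "A.t2"))
  expect_equal(genome_bulk_stats(iso)$total_exonic_bp, 150)

  sim <- simulate_annotated_genome(21, n_genes = 2000,
                                   single_exon_fraction = 0.30,
                                   nested_fraction = 0)
  st2 <- genome_bulk_stats(sim$ann)
  expect_equal(st2$single_exon_transcript_count, sim$truth$single_exon_tx)
  frac <- st2$single_exon_transcript_count / st2$transcript_count
  ci <- 4 * sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(frac - 0.30), ci)
})

test_that("intron profiles deduplicate shared introns", {
  ann <- make_ann(exon_row("A", c(0, 800), c(200, 900), tx = "A.t1"),
                  exon_row("A", c(100, 800), c(200, 900), tx = "A.t2"),
                  exon_row("B", c(1000, 1500), c(1100, 1600)))
  pr <- scaffold_intron_profile(ann, "s1")
  expect_equal(pr$count, 2)  # (200,800) shared; (1100,1500) from B
  expect_equal(pr$total_length, 600 + 400)
  expect_equal(pr$lengths_sorted_desc, c(600, 400))
  expect_equal(pr$mean_length, 500)
  expect_error(scaffold_intron_profile(ann, "nope"), "nope")

  solo <- make_ann(exon_row("A", 0, 100))
  expect_equal(scaffold_intron_profile(solo, "s1")$count, 0)
})

test_that("N50 follows the cumulative-half convention", {
  cs <- assembly_contiguity(c(5, 4, 3, 2, 1), threshold = 4)
  expect_equal(cs$total_length, 15)
  expect_equal(cs$n50, 4)
  expect_equal(cs$scaffolds_over_threshold, 2)
  expect_equal(cs$fraction_over_threshold, 9 / 15)

  one <- assembly_contiguity(1234)
  expect_equal(one$n50, 1234)
  expect_equal(one$n50_over_total, 1)

  # k equal scaffolds: N50 equals that length for any k
  for (k in c(1, 2, 7, 30))
    expect_equal(assembly_contiguity(rep(100, k))$n50, 100)
})

test_that("contaminant screen combines GC and RNA-coverage evidence", {
  seqs <- sequence_set(c(
    bact = paste(rep("GC", 500), collapse = ""),      # GC 1.0
    low = paste(rep("AT", 500), collapse = ""),       # GC 0.0
    host = paste(rep("GCAT", 250), collapse = "")),   # GC 0.5
    alphabet = "nt")
  scr <- screen_contaminant_scaffolds(
    seqs, coverage = c(host = 50), gc_threshold = 0.40, cov_threshold = 1)
  expect_equal(scr$flagged_bacterial[scr$scaffold == "bact"], TRUE)
  expect_equal(scr$flagged_bacterial[scr$scaffold == "low"], FALSE)
  expect_equal(scr$flagged_bacterial[scr$scaffold == "host"], FALSE)
  expect_equal(nrow(scr), 3)  # full table regardless of flag

  # N bases are excluded from the GC denominator
  withN <- sequence_set(c(x = "GGCCNNNNNNNNNNAT"), alphabet = "nt")
  expect_equal(screen_contaminant_scaffolds(withN)$gc_fraction, 4 / 6)
})
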