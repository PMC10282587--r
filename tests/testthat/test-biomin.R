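test_that("composition frequencies cover standard residues only and sum to 1", {
  f <- aa_composition(c(hh = "HHHH", hd = "HDHD", hx = "HXHX"))
  expect_equal(f["hh", "H"], 1)
  expect_equal(f["hd", "H"], 0.5)
  expect_equal(f["hd", "D"], 0.5)
  expect_equal(f["hx", "H"], 1)           # X excluded from both sides
  expect_equal(attr(f, "length")[["hx"]], 2)
  expect_equal(unname(rowSums(f)), rep(1, 3), tolerance = 1e-9)
  expect_error(aa_composition(c(bad = "XXX")), "bad")

  # trailing stop stripped
  expect_equal(aa_composition(c(p = "AAAA*"))["p", "A"], 1)
})

test_that("nearest-rank percentiles follow the ceiling convention", {
  # 100 proteins with freq(H) = 0.00, 0.01, ..., 0.99 via H_i D_rest
  prots <- vapply(0:99, function(i)
    paste0(strrep("H", i), strrep("D", 100 - i)), "")
  names(prots) <- sprintf("p%03d", 0:99)
  tab <- reference_percentiles(sequence_set(prots, "aa"), q = 99)
  expect_equal(unname(tab$values["H"]), 0.98)  # 99th of 100 sorted values
  tab100 <- reference_percentiles(sequence_set(prots, "aa"), q = 100)
  expect_equal(unname(tab100$values["H"]), 0.99)  # maximum

  # constant distribution: percentile equals the constant
  const <- setNames(rep(paste0(strrep("A", 5), strrep("D", 95)), 120),
                    sprintf("c%03d", 1:120))
  tabc <- reference_percentiles(sequence_set(const, "aa"), q = 99)
  expect_equal(unname(tabc$values["A"]), 0.05)

  expect_error(reference_percentiles(
    sequence_set(prots[1:50], "aa")), "too small")
})

test_that("bias flagging gates on length and records biased residues", {
  sim <- simulate_proteome(15, n_proteins = 400, n_reference = 400,
                           planted_fraction = 0.05)
  rep <- flag_biased_proteins(sim$proteome, sim$truth$percentiles)
  flagged <- rep$report$protein[rep$report$flagged]
  expect_true(all(sim$truth$planted_ids %in% flagged))  # recall 100%
  # the planted residue is among the recorded biased residues
  for (id in sim$truth$planted_ids) {
    aas <- strsplit(rep$report$biased_aas[rep$report$protein == id], ",")[[1]]
    expect_true(sim$truth$planted_aa[[id]] %in% aas)
  }
  # flagged iff biased_aas non-empty
  expect_equal(rep$report$flagged, nzchar(rep$report$biased_aas))

  # a short protein is never flagged
  short <- sequence_set(c(tiny = strrep("H", 20)), "aa")
  rep2 <- flag_biased_proteins(short, sim$truth$percentiles, min_len = 50)
  expect_false(any(rep2$report$flagged))
})

test_that("self-screen flags about 1% per residue", {
  sim <- simulate_proteome(8, n_proteins = 1, n_reference = 2000,
                           planted_fraction = 0)
  rep <- flag_biased_proteins(sim$reference, sim$truth$percentiles)
  hits <- sweep(rep$freq, 2, sim$truth$percentiles$values, ">=")
  per_aa <- colMeans(hits)
  expect_true(all(per_aa >= 0.005), info = paste(round(per_aa, 4), collapse = " "))
  expect_true(all(per_aa <= 0.02), info = paste(round(per_aa, 4), collapse = " "))
})

test_that("candidate selection applies residue, significance and direction filters", {
  sim <- simulate_proteome(22, n_proteins = 600, n_reference = 600,
                           planted_fraction = 0.02)
  rep <- flag_biased_proteins(sim$proteome, sim$truth$percentiles)
  cand <- select_candidates(rep, sim$expr)
  expect_true(all(sim$truth$planted_ids %in% cand$protein))
  expect_true(all(cand$padj <= 1e-4))
  expect_true(all(cand$log2fc > 0))
  expect_equal(cand$padj, sort(cand$padj))
  # every reported biased residue is in the allowed set
  expect_true(all(unlist(strsplit(cand$biased_aas, ",")) %in%
                    c("D", "E", "H", "P", "S", "T")))

  # down-direction excludes the upregulated planted set
  down <- select_candidates(rep, sim$expr, direction = "down")
  expect_false(any(sim$truth$planted_ids %in% down$protein))

  # flagged protein without an expression record warns and is excluded
  expr2 <- sim$expr[sim$expr$gene != sim$truth$planted_ids[1], ]
  expect_warning(cand2 <- select_candidates(rep, expr2), "without expression")
  expect_false(sim$truth$planted_ids[1] %in% cand2$protein)
})

test_that("cleavage scan cuts between the glycines of [VL]GG", {
  res <- scan_cleavage_sites("AAVGGAALGGAA")
  expect_equal(res$n_sites, 2)
  expect_equal(res$fragments$sequence, c("AAVG", "GAALG", "GAA"))
  expect_equal(paste(res$fragments$sequence, collapse = ""), "AAVGGAALGGAA")

  none <- scan_cleavage_sites("AAAHHHPPP")
  expect_equal(none$n_sites, 0)
  expect_equal(none$fragments$sequence, "AAAHHHPPP")

  # overlapping motifs all reported: VGGG has VGG at 1 (and GGG is no match)
  ovl <- scan_cleavage_sites("AVGGGA")
  expect_equal(ovl$n_sites, 1)
  ovl2 <- scan_cleavage_sites("VGGLGG")
  expect_equal(ovl2$n_sites, 2)
  expect_equal(ovl2$fragments$sequence, c("VG", "GLG", "G"))
})

test_that("mass prediction sums average residue masses plus water", {
  expect_equal(predict_mass("G"), 0.07507, tolerance = 1e-4)
  expect_equal(predict_mass(strrep("A", 10)) * 1000, 728.8, tolerance = 0.1)
  expect_error(predict_mass(""), "empty")
  expect_error(predict_mass("AAXAA"), "position 3")
})

test_that("fragments conserve sequence and mass", {
  set.seed(33)
  aas <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  for (i in 1:50) {
    prot <- paste(sample(aas, sample(50:300, 1), replace = TRUE),
                  collapse = "")
    res <- scan_cleavage_sites(prot)
    expect_equal(paste(res$fragments$sequence, collapse = ""), prot)
    expect_equal(nrow(res$fragments), res$n_sites + 1)
    # mass additivity: fragments re-add one water per cut
    expect_equal(sum(res$fragments$mass_kda),
                 predict_mass(prot) + res$n_sites * 18.0153 / 1000,
                 tolerance = 1e-9)
  }
})
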