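test_that("candidate variant selection is strict on F_ST and inclusive on depth", {
  v <- data.frame(chrom = "X", pos = 1:4, ref = "A", alt = "C",
                  fst = c(0.5, 0.6, 0.6, 0.9),
                  depth_p1 = c(30, 30, 19, 20),
                  depth_p2 = c(30, 30, 30, 20))
  kept <- select_candidate_variants(v)
  expect_equal(kept$pos, c(2L, 4L))  # F_ST == 0.5 excluded, depth 19 excluded
})

test_that("SNP effects are classified by hand-checkable translation", {
  fx <- effects_fixture()
  # CDS "ATG AAA TAG" on c1 (+): codon 2 spans genomic 6..8
  missense <- classify_variant("c1", 6, "A", "G", fx$genes, fx$genome)
  expect_equal(missense$effect, "missense")
  expect_equal(missense$codon_change, "AAA>GAA")
  expect_equal(missense$aa_change, "K2E")
  expect_equal(missense$impact, "moderate")

  nonsense <- classify_variant("c1", 6, "A", "T", fx$genes, fx$genome)
  expect_equal(nonsense$effect, "stop_gained")
  expect_equal(nonsense$impact, "high")

  silent <- classify_variant("c1", 8, "A", "G", fx$genes, fx$genome)
  expect_equal(silent$effect, "synonymous")
  expect_equal(silent$aa_change, "K2K")

  stoploss <- classify_variant("c1", 10, "A", "C", fx$genes, fx$genome)
  expect_equal(stoploss$effect, "stop_lost")

  outside <- classify_variant("c1", 15, "G", "A", fx$genes, fx$genome)
  expect_equal(outside$effect, "intergenic")
  expect_equal(outside$impact, "modifier")
})

test_that("reverse-strand classification mirrors the forward construction", {
  fx <- effects_fixture()
  # c2 gene "rev" carries the reverse complement of the c1 gene; genomic
  # position 6 on c1 (codon 2, first base) corresponds to c2 position
  # 2 + (11 - 6) + 1 = 8, with complemented alleles
  fwd <- classify_variant("c1", 6, "A", "G", fx$genes, fx$genome)
  rev <- classify_variant("c2", 8, "T", "C", fx$genes, fx$genome)
  expect_equal(rev$effect, fwd$effect)
  expect_equal(rev$codon_change, fwd$codon_change)
  expect_equal(rev$aa_change, fwd$aa_change)

  # systematic strand-symmetry sweep over every CDS position of the gene
  for (gpos in 3:11) {
    base_fwd <- substring(as.character(fx$genome[["c1"]]), gpos, gpos)
    alt_fwd <- setdiff(c("A", "C", "G", "T"), base_fwd)[1]
    mirror_pos <- 2 + (11 - gpos) + 1
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    a <- classify_variant("c1", gpos, base_fwd, alt_fwd, fx$genes, fx$genome)
    b <- classify_variant("c2", mirror_pos, unname(comp[base_fwd]),
                          unname(comp[alt_fwd]), fx$genes, fx$genome)
    expect_equal(b$effect, a$effect, label = paste("pos", gpos))
    expect_equal(b$aa_change, a$aa_change)
  }
})

test_that("indels are classified by frame arithmetic", {
  fx <- effects_fixture()
  # 3-bp deletion inside the c1 CDS: ref "GAAA" alt "G" anchored at pos 5
  del3 <- classify_variant("c1", 5, "GAAA", "G", fx$genes, fx$genome)
  expect_equal(del3$effect, "inframe_deletion")
  expect_equal(del3$impact, "moderate")
  ins3 <- classify_variant("c1", 5, "G", "GTTT", fx$genes, fx$genome)
  expect_equal(ins3$effect, "inframe_insertion")
  del1 <- classify_variant("c1", 5, "GA", "G", fx$genes, fx$genome)
  expect_equal(del1$effect, "frameshift")
  expect_equal(del1$impact, "high")
})

test_that("intronic and splice-adjacent positions are distinguished", {
  fx <- effects_fixture()
  # two-exon minus-strand gene on c2: intron spans genomic 26..33 (1-based)
  splice <- classify_variant("c2", 27, "G", "A", fx$genes, fx$genome)
  expect_equal(splice$effect, "splice_adjacent")
  mid <- classify_variant("c2", 30, "C", "T", fx$genes, fx$genome)
  expect_equal(mid$effect, "intronic")
})

test_that("a reference mismatch raises an error naming the position", {
  fx <- effects_fixture()
  expect_error(classify_variant("c1", 6, "C", "G", fx$genes, fx$genome),
               "c1:6")
})

test_that("classification is permutation-invariant and matches a curated fixture", {
  fx <- effects_fixture()
  variants <- data.frame(
    chrom = c("c1", "c1", "c1", "c1", "c1", "c2", "c2", "c2", "c2", "c1",
              "c2", "c2", "c1", "c1", "c2", "c2", "c1", "c2", "c1", "c2"),
    pos = c(6, 6, 8, 10, 15, 8, 27, 30, 20, 5,
            5, 24, 7, 9, 13, 35, 4, 21, 12, 3),
    ref = c("A", "A", "A", "A", "G", "T", "G", "C", "G", "GAAA",
            "A", "T", "A", "T", "G", "A", "T", "C", "G", "C"),
    alt = c("G", "T", "G", "C", "A", "C", "A", "T", "A", "G",
            "T", "A", "C", "C", "A", "G", "TAGC", "A", "GTT", "T"),
    stringsAsFactors = FALSE)
  expected <- c("missense", "stop_gained", "synonymous", "stop_lost",
                "intergenic", "missense", "splice_adjacent", "intronic",
                "synonymous", "inframe_deletion",
                "stop_lost", "missense", "missense", "stop_lost", "intergenic",
                "missense", "inframe_insertion", "missense", "intergenic",
                "synonymous")
  got <- classify_variants(variants, fx$genes, fx$genome)
  expect_equal(got$effect, expected)
  shuffle <- sample(nrow(variants))
  got2 <- classify_variants(variants[shuffle, ], fx$genes, fx$genome)
  expect_equal(got2$effect, expected[shuffle])
  counts1 <- table(got$effect)
  counts2 <- table(got2$effect)
  expect_equal(counts1, counts2)
})

test_that("per-gene summaries count effects and coverage per mode", {
  fx <- effects_fixture()
  variants <- data.frame(chrom = c("c1", "c1", "c1"), pos = c(6, 6, 8),
                         ref = c("A", "A", "A"), alt = c("G", "T", "G"),
                         stringsAsFactors = FALSE)
  eff <- classify_variants(variants, fx$genes, fx$genome)
  coords <- 1:20
  full <- matrix(30L, 20, 3)
  half <- full
  half[1:5, 2] <- 10L  # one CP population loses the first half of the gene
  summary_full <- per_gene_summary(eff, fx$genes["fwd"], depth_cp = full,
                                   depth_op = full, coords = coords,
                                   chrom = "c1")
  expect_equal(summary_full$missense, 1L)
  expect_equal(summary_full$nonsense, 1L)
  expect_equal(summary_full$frameshift, 0L)
  expect_equal(summary_full$pct_cp, 100)
  expect_equal(summary_full$pct_op, 100)

  summary_half <- per_gene_summary(eff, fx$genes["fwd"], depth_cp = half,
                                   depth_op = full, coords = coords,
                                   chrom = "c1")
  # gene spans 3..11 (9 bp); positions 3..5 fail in one CP population
  expect_equal(summary_half$pct_cp, 100 * 6 / 9)
  expect_equal(summary_half$pct_op, 100)

  none <- per_gene_summary(eff[0, ], fx$genes["fwd"])
  expect_equal(none$missense + none$nonsense + none$frameshift + none$inframe,
               0L)
})
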