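test_that("window construction enumerates fully contained windows", {
  w <- make_windows(50000, 20000, 5000)
  expect_equal(nrow(w), 7L)
  expect_equal(w$start[1], 0L)
  expect_equal(w$start[7], 30000L)
  expect_equal(w$end[7], 50000L)
  expect_equal(make_windows(100, 100)$end, 100L)
  expect_equal(nrow(make_windows(99, 100)), 0L)
})

test_that("nonoverlapping window SNP counts sum to the chromosome total", {
  set.seed(4)
  snp <- data.frame(chrom = "X", pos = sample.int(1e6, 2000),
                    num = runif(2000), den = runif(2000) + 0.5)
  w <- fst_windows(snp, c(X = 1e6), size = 1e5, step = 1e5)
  expect_equal(sum(w$n_snps), nrow(snp))
  # window value is the ratio of summed components
  in_w1 <- snp$pos <= 1e5
  expect_equal(w$fst[1], sum(snp$num[in_w1]) / sum(snp$den[in_w1]))
})

test_that("candidate delimitation handles empty, single and split signals", {
  w <- data.frame(chrom = "X", start = seq(0, 45000, 5000),
                  end = seq(20000, 65000, 5000), fst = 0.1)
  expect_equal(nrow(delimit_candidate_region(w)), 0L)

  w$fst[3:5] <- 0.4  # one overlapping run
  r <- delimit_candidate_region(w)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, w$start[3])
  expect_equal(r$end, w$end[5])
  expect_equal(r$mean_fst, 0.4)

  # two blocks separated by more than a window
  w$fst <- 0.1
  w$fst[c(1, 9)] <- 0.5
  r2 <- delimit_candidate_region(w)
  expect_equal(nrow(r2), 2L)
})

test_that("delimitation ignores NA windows and input order", {
  w <- data.frame(chrom = "X", start = seq(0, 45000, 5000),
                  end = seq(20000, 65000, 5000), fst = 0.1)
  w$fst[4:6] <- 0.5
  base <- delimit_candidate_region(w)
  w_na <- rbind(w, data.frame(chrom = "X", start = 70000, end = 90000,
                              fst = NA))
  shuffled <- w_na[sample.int(nrow(w_na)), ]
  expect_equal(delimit_candidate_region(shuffled), base)
})

test_that("association scores confirm regions and SNP F_ST trims boundaries", {
  w <- data.frame(chrom = "X", start = c(0, 5000, 30000),
                  end = c(20000, 25000, 50000), fst = c(0.4, 0.4, 0.4))
  assoc <- data.frame(chrom = "X", pos = c(10000, 11000, 40000),
                      score = c(80, 90, 10))
  r <- delimit_candidate_region(w, assoc = assoc, min_assoc = 2)
  expect_equal(nrow(r), 1L)  # second run has no associated SNP
  expect_equal(r$n_assoc, 2L)

  snp_fst <- data.frame(chrom = "X", pos = c(2000, 9000, 24000),
                        fst = c(0.2, 0.9, 0.8))
  r2 <- delimit_candidate_region(w, snp_fst = snp_fst, assoc = assoc,
                                 min_assoc = 2)
  expect_equal(r2$start, 9000 - 1)
  expect_equal(r2$end, 24000)
})

test_that("the scan localizes the simulated candidate block", {
  truth <- small_truth(1)
  sync <- merge_replicate_libraries(sample_pools(truth), truth$metadata)
  snps <- filter_snps(call_snps(sync))
  fst <- fst_by_mode(snps)
  lens <- setNames(rep(truth$config$chrom_length, 2), c("chr1", "X"))
  wins <- fst_windows(fst$snp, lens, 20000, 5000)
  regions <- delimit_candidate_region(wins, fst$snp)
  expect_equal(nrow(regions), 1L)
  ci <- truth$config$candidate_interval
  expect_equal(regions$chrom, ci$chrom)
  expect_lt(abs(regions$start - ci$start), 20000)
  expect_lt(abs(regions$end - ci$end), 20000)
})

test_that("depth ratio is 0.5 for equal copy number and drops with OP loss", {
  set.seed(6)
  n <- 50000
  op <- rpois(n, 30)
  cp <- rpois(n, 30)
  w <- depth_ratio_scan(op, cp, window = 2000)
  expect_equal(nrow(w), 25L)
  expect_lt(abs(mean(w$ratio) - 0.5), 0.01)

  # equal normalized depths -> exactly 0.5 everywhere
  w_eq <- depth_ratio_scan(rep(10, 4000), rep(20, 4000), window = 2000)
  expect_equal(w_eq$ratio, c(0.5, 0.5))

  # OP depth zero over a window -> ratio 0 there
  op0 <- c(rep(0, 2000), rep(30, 2000))
  cp0 <- rep(30, 4000)
  w0 <- depth_ratio_scan(op0, cp0, window = 2000, norm_op = 30, norm_cp = 30)
  expect_equal(w0$ratio[1], 0)

  # halved OP copy number -> 0.5x/(0.5x + x) = 1/3
  op_half <- rpois(n, 15)
  w_half <- depth_ratio_scan(op_half, cp, window = 2000,
                             norm_op = 30, norm_cp = 30)
  expect_lt(abs(mean(w_half$ratio) - 1 / 3), 0.01)
})

test_that("rank-sum comparisons match the exact null and edge cases", {
  wins <- data.frame(chrom = "X", start = seq(0, 19) * 1000,
                     end = seq(1, 20) * 1000, fst = rep(0.2, 20))
  region <- data.frame(chrom = "X", start = 0, end = 8000)
  same <- suppressWarnings(compare_candidate_vs_rest(wins, region))
  expect_equal(same$p_value, 1)

  # disjoint supports: U hits an extreme of [0, m*n]
  wins$fst[1:8] <- 1
  sep <- compare_candidate_vs_rest(wins, region)
  expect_true(sep$U %in% c(0, 8 * 12))
  expect_equal(sep$median_in, 1)
  expect_equal(sep$median_out, 0.2)

  set.seed(8)
  x <- runif(4)
  y <- runif(5)
  wins2 <- data.frame(chrom = "X", start = c(seq_along(x), 100 + seq_along(y)),
                      end = c(seq_along(x), 100 + seq_along(y)) + 0.5,
                      fst = c(x, y))
  region2 <- data.frame(chrom = "X", start = 0, end = 50)
  got <- compare_candidate_vs_rest(wins2, region2)
  expect_equal(got$p_value, oracle_mann_whitney_p(x, y), tolerance = 1e-9)

  paired <- compare_modes_paired(c(1, 2, 3, 4), c(1.5, 2.5, 3.5, 4.5))
  expect_true(is.finite(paired$p_value))
  expect_equal(paired$median_x, 2.5)
})
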