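test_that("Nei F_ST matches hand computation and its bounds", {
  expect_equal(fst_snp(0.9, 0.1, estimator = "nei"), (0.5 - 0.18) / 0.5)
  expect_equal(fst_snp(0.3, 0.3, estimator = "nei"), 0)
  expect_true(is.na(fst_snp(0, 0, estimator = "nei")))
  set.seed(1)
  p1 <- runif(500)
  p2 <- runif(500)
  f <- fst_snp(p1, p2, estimator = "nei")
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
})

test_that("the pool-corrected estimator converges to Nei at large depth and pool size", {
  set.seed(2)
  p1 <- runif(200, 0.05, 0.95)
  p2 <- runif(200, 0.05, 0.95)
  nei <- fst_snp(p1, p2, estimator = "nei")
  pc <- fst_snp(p1, p2, d1 = 1e4, d2 = 1e4, n1 = 1e4, n2 = 1e4,
                estimator = "pool_corrected")
  expect_lt(max(abs(pc - nei)), 1e-3)
  strong <- nei > 0.05  # relative agreement away from the F_ST ~ 0 regime
  expect_lt(max(abs(pc[strong] - nei[strong]) / nei[strong]), 0.01)
})

test_that("the pool-corrected estimator removes the finite-sampling bias", {
  # undifferentiated truth sampled through a finite pool and finite depth:
  # Nei is inflated, the corrected estimator is centred near zero and never
  # drops below -0.1 at depth >= 20
  set.seed(3)
  n_sites <- 4000
  p <- runif(n_sites, 0.1, 0.9)
  n1 <- 110; n2 <- 84; d <- 40
  p1 <- rbinom(n_sites, d, rbinom(n_sites, n1, p) / n1) / d
  p2 <- rbinom(n_sites, d, rbinom(n_sites, n2, p) / n2) / d
  nei <- fst_multilocus(p1, p2, estimator = "nei")
  pc <- fst_multilocus(p1, p2, d, d, n1, n2, estimator = "pool_corrected")
  expect_lt(abs(pc), abs(nei))
  expect_lt(abs(pc), 0.01)
  per_snp <- fst_snp(p1, p2, d, d, n1, n2)
  expect_gt(min(per_snp, na.rm = TRUE), -0.1 - 1e-9)
})

test_that("multilocus F_ST is a ratio of sums, not a mean of ratios", {
  p1 <- c(0.9, 0.7)
  p2 <- c(0.1, 0.5)
  expect_equal(fst_multilocus(p1[1], p2[1], estimator = "nei"),
               fst_snp(p1[1], p2[1], estimator = "nei"))
  # duplicated SNP leaves the ratio unchanged
  expect_equal(fst_multilocus(rep(p1[1], 2), rep(p2[1], 2), estimator = "nei"),
               fst_snp(p1[1], p2[1], estimator = "nei"))
  comp <- fst_components(p1, p2, estimator = "nei")
  expect_equal(fst_multilocus(p1, p2, estimator = "nei"),
               sum(comp$num) / sum(comp$den))
  expect_false(isTRUE(all.equal(fst_multilocus(p1, p2, estimator = "nei"),
                                mean(comp$fst, na.rm = TRUE))))
})

test_that("expected heterozygosity follows 1 - p^2 - q^2", {
  expect_equal(expected_heterozygosity(0.5), 0.5)
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(0.9), 0.18)
  expect_true(all(expected_heterozygosity(runif(100)) <= 0.5))
})

test_that("uniform-depth subsampling excludes out-of-range sites and is hypergeometric", {
  sub <- subsample_to_uniform_depth(k = c(5, 3, 10), depth = c(30, 19, 400),
                                    target = 30, max_depth = 360)
  expect_equal(sub$site, 1L)
  expect_equal(sub$k, 5L)  # depth == target is kept as-is
  set.seed(9)
  reps <- subsample_to_uniform_depth(rep(30, 1e4), rep(60, 1e4), target = 30)
  hyper_var <- 30 * 0.5 * 0.5 * 30 / 59
  se <- sqrt(hyper_var / 1e4)
  expect_lt(abs(mean(reps$k) - 15), 3 * se + 1e-9)
})

test_that("Tajima's D matches its closed form and the brute-force oracle", {
  # single singleton at n = 4: theta_pi = 0.5, theta_W = 1/a1
  d <- tajimas_d(k = 1, n = 4, min_count = 1)
  a1 <- 1 + 1 / 2 + 1 / 3
  expect_lt(d, 0)
  geno <- matrix(0L, 4, 1)
  geno[1, 1] <- 1L
  expect_equal(d, oracle_tajimas_d(geno))
  expect_equal(0.5 - 1 / a1, -0.5 / 11, tolerance = 1e-6)  # numerator check

  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    s <- sample(1:20, 1)
    geno <- matrix(rbinom(n * s, 1, runif(1, 0.2, 0.8)), n, s)
    k <- colSums(geno)
    poly <- k > 0 & k < n
    if (!any(poly)) next
    expect_equal(tajimas_d(pmin(k[poly], n - k[poly]), n, min_count = 1),
                 oracle_tajimas_d(geno), tolerance = 1e-12)
  }
})

test_that("Tajima's D honours min_count, coverage, and sample-size guards", {
  expect_true(is.na(tajimas_d(k = c(1, 1), n = 30, min_count = 2)))
  expect_true(is.na(tajimas_d(k = 10, n = 30, covered_fraction = 0.4)))
  expect_error(tajimas_d(k = 1, n = 3), "at least 4")
})

test_that("polarization picks the allele absent from the outgroup", {
  expect_equal(polarize("A", "C", 10L, 5L, "A"), 5L)
  expect_equal(polarize("A", "C", 10L, 5L, "C"), 10L)
  expect_true(is.na(polarize("A", "C", 10L, 5L, "G")))
  expect_true(is.na(polarize("A", "C", 10L, 5L, "N")))
})

test_that("Fay & Wu's H matches closed forms and flips sign under k <-> n-k", {
  h3 <- fay_wu_h(k = 3, n = 4, nolowfreq = 0)
  h1 <- fay_wu_h(k = 1, n = 4, nolowfreq = 0)
  expect_equal(h3, 0.5 - 1.5)
  expect_equal(h1, 0.5 - 2 / 12)
  expect_lt(h3, 0)
  expect_gt(h1, 0)
  geno <- matrix(0L, 4, 1)
  geno[1:3, 1] <- 1L
  expect_equal(h3, oracle_fay_wu_h(geno))

  set.seed(22)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    s <- sample(1:20, 1)
    geno <- matrix(rbinom(n * s, 1, runif(1, 0.2, 0.8)), n, s)
    k <- colSums(geno)
    expect_equal(fay_wu_h(k[k > 0 & k < n], n, nolowfreq = 0),
                 oracle_fay_wu_h(geno), tolerance = 1e-12)
  }
})

test_that("the low-frequency guard drops whole sites from H", {
  # all derived singletons excluded -> H computed on the remaining sites only
  expect_equal(fay_wu_h(k = c(1, 1, 10), n = 30, nolowfreq = 3),
               fay_wu_h(k = 10, n = 30, nolowfreq = 0))
  expect_true(is.na(fay_wu_h(k = c(1, 2, 3), n = 30, nolowfreq = 3)))
})

test_that("neutral-spectrum windows give near-zero D and H on average", {
  # windows of sites drawn from the unfolded neutral spectrum (P(k) ~ 1/k)
  # at the uniform sample size: both statistics are centred at zero, with all
  # frequency classes retained so the classical calibration applies
  set.seed(10)
  n <- 30
  kcl <- seq_len(n - 1)
  n_windows <- 1000  # the raw H sum is noisy; many windows for a tight mean
  d_vals <- h_vals <- numeric(n_windows)
  for (w in seq_len(n_windows)) {
    k <- sample(kcl, 100, replace = TRUE, prob = 1 / kcl)
    d_vals[w] <- tajimas_d(pmin(k, n - k), n, min_count = 1)
    h_vals[w] <- fay_wu_h(k, n, nolowfreq = 0)
  }
  expect_lt(abs(mean(d_vals)), 0.3)
  expect_lt(abs(mean(h_vals)), 0.3)
  # the sweep signature is directional: an excess of high-frequency derived
  # alleles pushes H negative
  h_sweep <- fay_wu_h(rep(c(26, 28), 50), n, nolowfreq = 0)
  expect_lt(h_sweep, -1)
})

test_that("pipeline-level windowed D and H respond to the candidate sweep", {
  # absolute pooled values are shifted by the subsample-then-classical
  # simplification and the error guards; the scan interprets them relative to
  # the genome background, where the candidate region must stand out in OP
  truth <- small_truth(1)
  sync <- merge_replicate_libraries(sample_pools(truth), truth$metadata)
  snps <- call_snps(sync)
  lens <- c(chr1 = truth$config$chrom_length, X = truth$config$chrom_length)
  set.seed(5)
  stats_op <- sfs_window_stats(snps, "OP", outgroup = truth$outgroup,
                               chrom_lengths = lens, size = 2e4)
  ci <- truth$config$candidate_interval
  in_cand <- stats_op$chrom == ci$chrom & stats_op$start >= ci$start &
    stats_op$end <= ci$end
  d_in <- mean(stats_op$tajimas_d[in_cand], na.rm = TRUE)
  d_out <- mean(stats_op$tajimas_d[!in_cand], na.rm = TRUE)
  expect_lt(d_in, d_out)
})
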