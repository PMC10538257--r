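test_that("mutation-rate composition obeys its defining identities", {
  r <- compose_mutation_rates(mu_parth = 1e-10, mu_parth_ci = c(1e-10, 1e-10),
                              mu_sex = 1e-10, mu_sex_ci = c(1e-10, 1e-10),
                              n_gen = 15)
  # equal per-generation rates collapse the two classes
  expect_equal(r$mu_cp[["estimate"]], r$mu_op[["estimate"]])
  expect_equal(r$mu_op[["estimate"]], 15 * 1e-10)
  r2 <- compose_mutation_rates()
  expect_equal(r2$mu_op[["estimate"]], 15 * 2.7e-10)
  expect_equal(r2$mu_cp[["estimate"]], 14 * 2.7e-10 + 2.96e-9)
  expect_equal(r2$mu_mean[["estimate"]],
               (r2$mu_op[["estimate"]] + r2$mu_cp[["estimate"]]) / 2)
  expect_true(r2$mu_mean[["lower"]] <= r2$mu_mean[["estimate"]])
  expect_true(r2$mu_mean[["estimate"]] <= r2$mu_mean[["upper"]])
})

test_that("net divergence D_a behaves as defined", {
  # fraction f of fixed differences, no polymorphism -> D_a = f
  p_op <- c(rep(1, 3), rep(0, 7))
  p_cp <- rep(0, 10)
  expect_equal(net_divergence_da(p_op, p_cp)$da, 0.3)
  # identical frequency tracks -> D_a = 0
  p <- runif(50)
  expect_equal(net_divergence_da(p, p)$da,
               mean(2 * p * (1 - p)) - mean(2 * p * (1 - p)))
  # hand case: one site 0.9/0.1 among 10 sites -> D_xy equals mean pi
  p1 <- c(0.9, rep(0, 9))
  p2 <- c(0.1, rep(0, 9))
  res <- net_divergence_da(p1, p2)
  expect_equal(res$dxy, 0.82 / 10)
  expect_equal(res$da, res$dxy - (res$pi_op + res$pi_cp) / 2)
})

test_that("time from D_a is D_a / (2 mu) and scales inversely with mu", {
  rates <- compose_mutation_rates(mu_parth = 5e-9 / 15,
                                  mu_parth_ci = c(4e-9, 6e-9) / 15,
                                  mu_sex = 5e-9 / 15,
                                  mu_sex_ci = c(4e-9, 6e-9) / 15)
  expect_equal(rates$mu_mean[["estimate"]], 5e-9)
  est <- time_from_da(1e-3, rates)
  expect_equal(est$t_years, 1e5)
  expect_equal(time_from_da(0, rates)$t_years, 0)
  rates2 <- compose_mutation_rates(mu_parth = 2 * 5e-9 / 15,
                                   mu_parth_ci = c(4e-9, 16e-9) / 15,
                                   mu_sex = 2 * 5e-9 / 15,
                                   mu_sex_ci = c(4e-9, 16e-9) / 15)
  expect_equal(time_from_da(1e-3, rates2)$t_years, est$t_years / 2)
  expect_true(est$ci95[["lower"]] <= est$t_years)
  expect_true(est$t_years <= est$ci95[["upper"]])
})

test_that("consensus draws are seeded, respect fixation, and differ at rate p(1-q)+q(1-p)", {
  p_op <- rep(1, 100)
  p_cp <- rep(0, 100)
  set.seed(1)
  pair <- draw_consensus(p_op, p_cp)
  expect_true(all(pair$op))
  expect_false(any(pair$cp))
  expect_equal(count_substitutions(pair), 100L)

  set.seed(42)
  a <- draw_consensus(runif(50), runif(50))
  set.seed(42)
  b <- draw_consensus(runif(50), runif(50))
  expect_identical(a, b)

  set.seed(3)
  diffs <- replicate(400, {
    pair <- draw_consensus(rep(0.5, 50), rep(0.5, 50))
    count_substitutions(pair) / 50
  })
  expect_lt(abs(mean(diffs) - 0.5), 3 * stats::sd(diffs) / sqrt(400))
})

test_that("substitution counting respects the callable mask", {
  p_op <- c(1, 1, 1, 0)
  p_cp <- c(0, 0, 0, 0)
  mask <- c(TRUE, FALSE, TRUE, TRUE)
  set.seed(1)
  pair <- draw_consensus(p_op, p_cp, mask)
  expect_equal(count_substitutions(pair), 2L)
  expect_equal(pair$mask_index, c(1L, 3L, 4L))
})

test_that("expected substitution count equals sum of per-site difference probabilities", {
  set.seed(77)
  n_sites <- 1e4
  p_op <- runif(n_sites)
  p_cp <- runif(n_sites)
  expected <- sum(p_op * (1 - p_cp) + p_cp * (1 - p_op))
  counts <- vapply(1:200, function(s) {
    set.seed(s)
    count_substitutions(draw_consensus(p_op, p_cp))
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("substitution-count dating is linear and zero at zero", {
  rates <- compose_mutation_rates()
  expect_equal(time_from_counts(0, 1e5, rates)$t_years, 0)
  t1 <- time_from_counts(100, 1e5, rates)$t_years
  t2 <- time_from_counts(200, 1e5, rates)$t_years
  expect_equal(t2, 2 * t1)
  reps <- c(90, 100, 110)
  est <- time_from_counts(reps, 1e5, rates)
  expect_equal(est$inputs$n_mutated, 100)
  expect_true(est$ci95[["lower"]] < est$t_years)
  expect_true(est$ci95[["upper"]] > est$t_years)
  # conservative combined CI is wider than either single-source CI
  expect_lte(est$ci95[["lower"]], est$inputs$t_ci_n_only[1])
  expect_gte(est$ci95[["upper"]], est$inputs$t_ci_n_only[2])
})

test_that("dating recovers the truth for sequences diverged under Jukes-Cantor", {
  rates <- compose_mutation_rates(mu_parth = 5e-9 / 15,
                                  mu_parth_ci = c(5e-9, 5e-9) / 15,
                                  mu_sex = 5e-9 / 15,
                                  mu_sex_ci = c(5e-9, 5e-9) / 15)
  mu <- rates$mu_mean[["estimate"]]
  t_true <- 1e6  # 2*T*mu = 0.01
  n_sites <- 2e5
  set.seed(13)
  # JC: probability a site shows a difference after divergence 2*T*mu
  d <- 2 * t_true * mu
  p_diff <- 3 / 4 * (1 - exp(-4 / 3 * d))
  n_mut <- rbinom(1, n_sites, p_diff)
  est <- time_from_counts(n_mut, n_sites, rates)
  se_t <- sqrt(n_sites * p_diff * (1 - p_diff)) / (2 * n_sites * mu)
  expect_lt(abs(est$t_years - t_true), 2 * se_t + 0.02 * t_true)
})

test_that("dS-calibrated dating maps through the calibration point", {
  expect_equal(time_from_ds(0)$t_years, 0)
  expect_equal(time_from_ds(0.2268)$t_years, 22e6)
  est <- time_from_ds(0.01, ds_ci = c(0.008, 0.012))
  expect_equal(est$t_years, 0.01 / 0.2268 * 22e6)
  expect_equal(unname(est$ci95), c(0.008, 0.012) / 0.2268 * 22e6)
})

test_that("NG86 counting matches hand-derived cases", {
  # identical sequences
  same <- ng86_distance("ATGAAAGGGTTT", "ATGAAAGGGTTT")
  expect_equal(same$Sd, 0)
  expect_equal(same$ds, 0)
  # one synonymous third-position change: S = 5/3 sites over ATG AAA GGG TTT
  res <- ng86_distance("ATGAAAGGGTTT", "ATGAAGGGGTTT")
  expect_equal(res$S, (0 + 1 / 3 + 1 + 1 / 3 + 0 + 1 / 3 + 1 + 1 / 3) / 2)
  expect_equal(res$Sd, 1)
  expect_equal(res$Nd, 0)
  expect_equal(res$ds, -3 / 4 * log(1 - 4 / 3 * (1 / res$S)))
  # nonsynonymous-only change -> dS = 0
  res2 <- ng86_distance("ATGAAAGGGTTT", "ATGGAAGGGTTT")
  expect_equal(res2$Sd, 0)
  expect_equal(res2$ds, 0)
  expect_gt(res2$dn, 0)
  # terminal stop codons are trimmed, premature stops rejected
  expect_equal(ng86_distance("ATGAAATAA", "ATGAAGTAA")$Sd, 1)
  expect_error(ng86_distance("ATGTAAAAA", "ATGTAAAAG"), "premature stop")
})

test_that("NG86 pathway counts agree with brute-force enumeration (random codon pairs)", {
  # the exhaustive 61 x 61 sweep runs in the acceptance suite
  set.seed(19)
  codons <- poolscan:::SENSE_CODONS
  pairs <- cbind(sample(codons, 150, replace = TRUE),
                 sample(codons, 150, replace = TRUE))
  for (i in seq_len(nrow(pairs))) {
    got <- poolscan:::ng86_pair_cached(pairs[i, 1], pairs[i, 2])
    want <- oracle_ng86_path(pairs[i, 1], pairs[i, 2])
    expect_equal(unname(got), unname(want),
                 label = paste(pairs[i, 1], pairs[i, 2]), tolerance = 1e-12)
  }
})

test_that("per-gene dS summarizes genes and skips broken ones", {
  cds_op <- c(g1 = "ATGAAAGGGTTT", g2 = "ATGTAAAAATTT", g3 = "ATGCCCGGGAAA")
  cds_cp <- c(g1 = "ATGAAGGGGTTT", g2 = "ATGTAAAAGTTT", g3 = "ATGCCCGGGAAA")
  expect_warning(tab <- pairwise_ds(cds_op, cds_cp), "premature stop")
  expect_true(is.na(tab$ds[2]))
  expect_equal(tab$ds[3], 0)
  expect_gt(tab$ds[1], 0)
  expect_equal(attr(tab, "median_ds"), median(tab$ds, na.rm = TRUE))
})

test_that("the LWL85 option delegates to seqinr and agrees on zero divergence", {
  skip_if_not_installed("seqinr")
  cds <- c(g1 = "ATGAAAGGGTTTCCCAAA")
  same <- pairwise_ds(cds, cds, method = "LWL85")
  expect_equal(same$ds, 0)
  far <- pairwise_ds(c(g1 = "ATGAAAGGGTTTCCCAAA"),
                     c(g1 = "ATGAAGGGATTCCCGAAA"), method = "LWL85")
  expect_gt(far$ds, 0)
})

test_that("all three estimators date an identical, monomorphic region at zero", {
  rates <- compose_mutation_rates()
  p <- rep(0, 200)
  expect_equal(time_from_da(net_divergence_da(p, p)$da, rates)$t_years, 0)
  set.seed(1)
  pair <- draw_consensus(p, p)
  expect_equal(time_from_counts(count_substitutions(pair), 200, rates)$t_years, 0)
  expect_equal(time_from_ds(0)$t_years, 0)
})

test_that("end-to-end dating of a simulated region returns coherent estimates", {
  truth <- small_truth(1)
  sync <- merge_replicate_libraries(sample_pools(truth), truth$metadata)
  snps <- call_snps(sync)
  rates <- compose_mutation_rates()
  ci <- truth$config$candidate_interval
  res <- date_region(snps, ci, truth$genome, truth$genes, rates,
                     n_replicates = 20, seed = 4)
  expect_equal(length(res$n_mutated), 20L)
  expect_gt(res$substitution_count$t_years, 0)
  expect_true(res$substitution_count$ci95[["lower"]] <=
                res$substitution_count$t_years)
  expect_gt(res$da$t_years, 0)
  if (!is.null(res$ds_calibrated)) {
    expect_gte(res$ds_calibrated$t_years, 0)
  }
})
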