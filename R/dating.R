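#' Compose per-year mutation rates from per-generation rates
#'
#' An obligate parthenogen goes through `n_gen` parthenogenetic generations a
#' year, a cyclical parthenogen through `n_gen - 1` parthenogenetic plus one
#' sexual generation, so
#' `mu_op = n_gen * mu_parth`,
#' `mu_cp = (n_gen - 1) * mu_parth + mu_sex`, and the rate separating the two
#' allelic classes is their mean. Confidence bounds are composed by applying
#' the same formulas to the bound values of the per-generation rates.
#'
#' Defaults are the experimentally estimated parthenogenetic rate for the pea
#' aphid and the insect average per sexual generation.
#'
#' @param mu_parth substitutions/site/parthenogenetic generation, with 95% CI.
#' @param mu_sex substitutions/site/sexual generation, with 95% CI.
#' @param n_gen generations per year.
#' @return object of class `mutation_rates` with elements `mu_op`, `mu_cp`,
#'   `mu_mean` (each `c(estimate, lower, upper)` per year) and the inputs.
#' @export
compose_mutation_rates <- function(mu_parth = 2.7e-10,
                                   mu_parth_ci = c(1.9e-10, 3.5e-10),
                                   mu_sex = 2.96e-9,
                                   mu_sex_ci = c(1.52e-9, 4.99e-9),
                                   n_gen = 15) {
  stopifnot(mu_parth_ci[1] <= mu_parth, mu_parth <= mu_parth_ci[2],
            mu_sex_ci[1] <= mu_sex, mu_sex <= mu_sex_ci[2])
  comp <- function(mp, ms) {
    mu_op <- n_gen * mp
    mu_cp <- (n_gen - 1) * mp + ms
    c(op = mu_op, cp = mu_cp, mean = (mu_op + mu_cp) / 2)
  }
  est <- comp(mu_parth, mu_sex)
  lo <- comp(mu_parth_ci[1], mu_sex_ci[1])
  hi <- comp(mu_parth_ci[2], mu_sex_ci[2])
  structure(list(
    mu_op = c(estimate = est[["op"]], lower = lo[["op"]], upper = hi[["op"]]),
    mu_cp = c(estimate = est[["cp"]], lower = lo[["cp"]], upper = hi[["cp"]]),
    mu_mean = c(estimate = est[["mean"]], lower = lo[["mean"]],
                upper = hi[["mean"]]),
    mu_parth = c(estimate = mu_parth, lower = mu_parth_ci[1],
                 upper = mu_parth_ci[2]),
    mu_sex = c(estimate = mu_sex, lower = mu_sex_ci[1], upper = mu_sex_ci[2]),
    n_gen = n_gen), class = "mutation_rates")
}

#' @export
print.mutation_rates <- function(x, ...) {
  cat(sprintf("per-year mutation rates (subs/site/year):\n"))
  for (nm in c("mu_op", "mu_cp", "mu_mean")) {
    v <- x[[nm]]
    cat(sprintf("  %-8s %.3g (95%% CI %.3g-%.3g)\n", nm, v["estimate"],
                v["lower"], v["upper"]))
  }
  invisible(x)
}

new_divergence_estimate <- function(method, t_years, ci95, inputs) {
  stopifnot(t_years >= 0, ci95[1] <= t_years + 1e-9, t_years <= ci95[2] + 1e-9)
  structure(list(method = method, t_years = t_years,
                 ci95 = c(lower = unname(ci95[1]), upper = unname(ci95[2])),
                 inputs = inputs),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("divergence time [%s]: %.0f years (95%% CI %.0f-%.0f)\n",
              x$method, x$t_years, x$ci95["lower"], x$ci95["upper"]))
  invisible(x)
}

#' Net divergence D_a between the two allelic classes
#'
#' `D_a = D_xy - (pi_1 + pi_2) / 2` where `D_xy` is the mean over callable
#' sites of `p1 (1 - p2) + p2 (1 - p1)` and `pi_i` the mean within-group
#' diversity `2 p_i (1 - p_i)`, all from pooled allele frequencies (no
#' pool-size correction).
#'
#' @param p_op,p_cp derived (or minor) allele frequencies per callable site;
#'   monomorphic callable sites enter as 0 (or 1).
#' @return list with `da`, `dxy`, `pi_op`, `pi_cp`, `n_sites`.
#' @export
net_divergence_da <- function(p_op, p_cp) {
  stopifnot(length(p_op) == length(p_cp))
  dxy <- mean(p_op * (1 - p_cp) + p_cp * (1 - p_op))
  pi_op <- mean(2 * p_op * (1 - p_op))
  pi_cp <- mean(2 * p_cp * (1 - p_cp))
  list(da = dxy - (pi_op + pi_cp) / 2, dxy = dxy, pi_op = pi_op,
       pi_cp = pi_cp, n_sites = length(p_op))
}

#' Divergence time from net divergence
#'
#' `T = D_a / (2 mu)`. The confidence interval propagates the CI of the
#' mutation rate (low rate, high time) and, when given, of D_a, taking the
#' conservative product of extremes.
#'
#' @param da net divergence (scalar), optionally with `da_ci` bounds.
#' @param rates a [compose_mutation_rates()] object (its `mu_mean` is used).
#' @param da_ci optional `c(lower, upper)` for D_a.
#' @return a `divergence_estimate`.
#' @export
time_from_da <- function(da, rates, da_ci = NULL) {
  mu <- rates$mu_mean
  t <- max(0, da / (2 * mu["estimate"]))  # sampling noise can push D_a < 0
  lo_da <- if (is.null(da_ci)) da else da_ci[1]
  hi_da <- if (is.null(da_ci)) da else da_ci[2]
  ci <- pmax(0, c(lo_da / (2 * mu["upper"]), hi_da / (2 * mu["lower"])))
  new_divergence_estimate("da", unname(t), ci,
                          list(da = da, da_ci = da_ci, mu = mu))
}

#' Draw consensus alleles for the two modes at polymorphic sites
#'
#' At every site one allele is drawn per mode, Bernoulli with success equal to
#' that mode's allele frequency (a haploid consensus). Deterministic under the
#' caller's seed.
#'
#' @param p_op,p_cp derived-allele frequencies per site.
#' @param mask logical callable mask (sites outside it are dropped).
#' @return list with logical vectors `op`, `cp` (TRUE = derived allele drawn)
#'   and `mask_index` (indices of the retained sites).
#' @export
draw_consensus <- function(p_op, p_cp, mask = rep(TRUE, length(p_op))) {
  stopifnot(length(p_op) == length(p_cp), length(mask) == length(p_op))
  idx <- which(mask)
  list(op = rbinom(length(idx), 1, p_op[idx]) == 1L,
       cp = rbinom(length(idx), 1, p_cp[idx]) == 1L,
       mask_index = idx)
}

#' Count substitutions between a consensus pair
#'
#' Hamming distance between the op and cp consensus draws, restricted to the
#' callable mask used to build them.
#'
#' @param pair result of [draw_consensus()].
#' @return integer substitution count.
#' @export
count_substitutions <- function(pair) {
  sum(pair$op != pair$cp)
}

#' Divergence time from consensus substitution counts
#'
#' `T = N_mutated / (2 N_sites mu)`. The point estimate uses the replicate
#' mean of `N_mutated`; the combined CI takes the conservative product of
#' extremes (2.5th replicate percentile of N with the upper mu bound, 97.5th
#' with the lower bound). The N-only and mu-only intervals are also reported
#' in `$inputs`.
#'
#' @param n_mutated substitution counts; a vector over consensus replicates
#'   (or a scalar).
#' @param n_sites number of callable sites.
#' @param rates a [compose_mutation_rates()] object.
#' @return a `divergence_estimate`.
#' @export
time_from_counts <- function(n_mutated, n_sites, rates) {
  stopifnot(n_sites > 0, all(n_mutated >= 0))
  mu <- rates$mu_mean
  n_point <- mean(n_mutated)
  n_ci <- if (length(n_mutated) > 1) {
    unname(quantile(n_mutated, c(0.025, 0.975)))
  } else c(n_mutated, n_mutated)
  t <- n_point / (2 * n_sites * mu["estimate"])
  ci <- c(n_ci[1] / (2 * n_sites * mu["upper"]),
          n_ci[2] / (2 * n_sites * mu["lower"]))
  new_divergence_estimate(
    "substitution_count", unname(t), ci,
    list(n_mutated = n_point, n_mutated_ci = n_ci, n_sites = n_sites, mu = mu,
         t_ci_n_only = unname(n_ci / (2 * n_sites * mu["estimate"])),
         t_ci_mu_only = unname(c(n_point / (2 * n_sites * mu["upper"]),
                                 n_point / (2 * n_sites * mu["lower"])))))
}

#' Divergence time from calibrated synonymous divergence
#'
#' Assuming a constant synonymous rate, `T = (dS / dS_cal) * T_cal` where the
#' calibration pair has known divergence time `T_cal` and synonymous distance
#' `dS_cal`. Defaults use the pea aphid / peach-potato aphid calibration
#' (dS = 0.2268 at 22 My).
#'
#' @param ds median synonymous divergence between the two allelic classes.
#' @param ds_ci optional `c(lower, upper)` replicate CI for dS.
#' @param ds_cal,t_cal calibration dS and time (years).
#' @return a `divergence_estimate`.
#' @export
time_from_ds <- function(ds, ds_ci = NULL, ds_cal = 0.2268, t_cal = 22e6) {
  stopifnot(ds >= 0, ds_cal > 0, t_cal > 0)
  t <- ds / ds_cal * t_cal
  ci <- if (is.null(ds_ci)) c(t, t) else ds_ci / ds_cal * t_cal
  new_divergence_estimate("ds_calibrated", t, ci,
                          list(ds = ds, ds_ci = ds_ci, ds_cal = ds_cal,
                               t_cal = t_cal))
}

#' Consensus genome sequences for the two modes over a region
#'
#' Builds op and cp haploid consensus sequences of a genomic interval by
#' substituting, at every polymorphic SNP, the allele drawn by
#' [draw_consensus()] into the reference sequence.
#'
#' @param genome named `DNAStringSet` reference.
#' @param region `list(chrom =, start =, end =)`, 0-based half-open.
#' @param snp_pos 1-based positions of the SNPs (on `region$chrom`).
#' @param allele_ref,allele_alt reference-orientation alleles at the SNPs
#'   (drawn=FALSE keeps `allele_ref`, drawn=TRUE writes `allele_alt`).
#' @param pair a [draw_consensus()] result over those SNPs.
#' @return `DNAStringSet` of two sequences named `op`, `cp`, in genome
#'   coordinates of the region.
#' @export
consensus_sequences <- function(genome, region, snp_pos, allele_ref,
                                allele_alt, pair) {
  base <- Biostrings::subseq(genome[[region$chrom]], region$start + 1L,
                             region$end)
  idx <- pair$mask_index
  rel <- snp_pos[idx] - region$start  # 1-based within region
  inside <- rel >= 1 & rel <= length(base)
  build <- function(drawn) {
    letters <- ifelse(drawn, allele_alt[idx], allele_ref[idx])
    s <- base
    if (any(inside)) {
      s <- Biostrings::replaceLetterAt(s, rel[inside], letters[inside])
    }
    s
  }
  out <- Biostrings::DNAStringSet(list(op = build(pair$op),
                                       cp = build(pair$cp)))
  out
}

#' Date the divergence of the two allelic classes of a candidate region
#'
#' Runs the three estimators on a region: (1) net divergence D_a from the
#' pooled frequencies, (2) substitution counts between op/cp consensus
#' sequences over `n_replicates` random draws, (3) calibrated median dS over
#' the region's genes computed on the same consensus replicates.
#'
#' @param snps a `snp_table` restricted (internally) to the region.
#' @param region `list(chrom =, start =, end =)`, 0-based half-open.
#' @param genome named `DNAStringSet` reference.
#' @param genes a `gene_models` object (for dS); genes outside the region are
#'   ignored.
#' @param rates a [compose_mutation_rates()] object.
#' @param n_sites number of callable sites of the region (depth >= 20 in every
#'   population); when NULL, the region width is used.
#' @param n_replicates consensus replicates (default 100).
#' @param seed seed for the consensus draws.
#' @param ds_cal,t_cal calibration for the dS clock.
#' @return list of three `divergence_estimate`s (`da`, `substitution_count`,
#'   `ds_calibrated`) plus `n_mutated` (replicate vector) and `ds` (replicate
#'   vector of median dS).
#' @export
date_region <- function(snps, region, genome, genes, rates,
                        n_sites = NULL, n_replicates = 100, seed = 1,
                        ds_cal = 0.2268, t_cal = 22e6) {
  in_region <- snps$info$chrom == region$chrom &
    (snps$info$pos - 1L) >= region$start & (snps$info$pos - 1L) < region$end
  snps <- subset_snps(snps, in_region)
  if (is.null(n_sites)) n_sites <- region$end - region$start
  mf <- mode_frequencies(snps)
  p_op <- mf$p[, "OP"]
  p_cp <- mf$p[, "CP"]

  # (1) D_a over callable sites: polymorphic sites contribute their
  # frequencies, monomorphic callable sites contribute 0 to every term.
  poly <- net_divergence_da(p_op, p_cp)
  da <- (poly$dxy * length(p_op)) / n_sites -
    ((poly$pi_op + poly$pi_cp) / 2 * length(p_op)) / n_sites
  est_da <- time_from_da(da, rates)

  # minor allele in reference orientation: drawn = TRUE writes the minor
  # allele; frequencies are minor-allele frequencies per mode
  region_genes <- Filter(function(g) {
    g$chrom == region$chrom && min(g$cds$start) >= region$start &&
      max(g$cds$end) <= region$end && g$usable
  }, genes)

  set.seed(seed)
  n_mutated <- integer(n_replicates)
  ds_reps <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    pair <- draw_consensus(p_op, p_cp)
    n_mutated[r] <- count_substitutions(pair)
    if (length(region_genes) > 0) {
      cons <- consensus_sequences(genome, region, snps$info$pos,
                                  snps$info$major, snps$info$minor, pair)
      shifted <- lapply(region_genes, function(g) {
        g$cds$start <- g$cds$start - region$start
        g$cds$end <- g$cds$end - region$start
        g
      })
      gene_ds <- vapply(shifted, function(g) {
        cds_op <- cds_sequence(g, setNames(Biostrings::DNAStringSet(cons[["op"]]), g$chrom))
        cds_cp <- cds_sequence(g, setNames(Biostrings::DNAStringSet(cons[["cp"]]), g$chrom))
        res <- tryCatch(ng86_distance(as.character(cds_op), as.character(cds_cp)),
                        error = function(e) NULL)
        if (is.null(res)) NA_real_ else res$ds
      }, numeric(1))
      ds_reps[r] <- median(gene_ds, na.rm = TRUE)
    }
  }

  est_counts <- time_from_counts(n_mutated, n_sites, rates)
  est_ds <- NULL
  if (any(!is.na(ds_reps))) {
    ds_point <- median(ds_reps, na.rm = TRUE)
    ds_ci <- unname(quantile(ds_reps, c(0.025, 0.975), na.rm = TRUE))
    est_ds <- time_from_ds(ds_point, ds_ci, ds_cal, t_cal)
  }
  list(da = est_da, substitution_count = est_counts, ds_calibrated = est_ds,
       n_mutated = n_mutated, ds = ds_reps)
}
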