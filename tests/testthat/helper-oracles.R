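# Independent brute-force oracles used to check the estimators.

# Tajima's D from an explicit haplotype matrix (rows = haplotypes, cols =
# sites, entries 0/1), via pairwise differences counted with loops.
oracle_tajimas_d <- function(geno) {
  n <- nrow(geno)
  pi_sum <- 0
  n_pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pi_sum <- pi_sum + sum(geno[i, ] != geno[j, ])
      n_pairs <- n_pairs + 1
    }
  }
  theta_pi <- pi_sum / n_pairs
  counts <- colSums(geno)
  s <- sum(counts > 0 & counts < n)
  if (s == 0) return(NA_real_)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- c1 / a1 * s + c2 / (a1^2 + a2) * s * (s - 1)
  (theta_pi - s / a1) / sqrt(v)
}

# Fay & Wu's H from a polarized haplotype matrix (1 = derived): theta_pi via
# explicit pairwise loops, theta_H via the derived-allele site frequency
# spectrum.
oracle_fay_wu_h <- function(geno) {
  n <- nrow(geno)
  pi_sum <- 0
  n_pairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pi_sum <- pi_sum + sum(geno[i, ] != geno[j, ])
      n_pairs <- n_pairs + 1
    }
  }
  theta_pi <- pi_sum / n_pairs
  k <- colSums(geno)
  k <- k[k > 0 & k < n]
  if (length(k) == 0) return(NA_real_)
  theta_h <- sum(2 * k^2) / (n * (n - 1))
  theta_pi - theta_h
}

# NG86 pathway counting re-derived independently: Biostrings translation,
# recursion over difference positions (no shared code with the package).
oracle_ng86_path <- function(c1, c2) {
  trans <- function(codon) unname(Biostrings::GENETIC_CODE[codon])
  recurse <- function(cur) {
    diffs <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(diffs) == 0) {
      return(list(list(sd = 0, nd = 0, stop = FALSE)))
    }
    out <- list()
    for (pos in diffs) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      syn <- trans(cur) == trans(nxt) && trans(nxt) != "*" && trans(cur) != "*"
      hit_stop <- nxt != c2 && trans(nxt) == "*"
      for (tail in recurse(nxt)) {
        out[[length(out) + 1]] <- list(sd = tail$sd + as.numeric(syn),
                                       nd = tail$nd + as.numeric(!syn),
                                       stop = tail$stop || hit_stop)
      }
    }
    out
  }
  paths <- recurse(c1)
  keep <- Filter(function(p) !p$stop, paths)
  if (length(keep) == 0) keep <- paths
  c(Sd = mean(vapply(keep, `[[`, numeric(1), "sd")),
    Nd = mean(vapply(keep, `[[`, numeric(1), "nd")))
}

# exact Mann-Whitney p-value by exhaustive enumeration of group assignments
oracle_mann_whitney_p <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  pooled <- c(x, y)
  m <- length(x)
  combos <- utils::combn(length(pooled), m)
  mn <- m * length(y)
  count <- 0
  for (i in seq_len(ncol(combos))) {
    u <- u_stat(pooled[combos[, i]], pooled[-combos[, i]])
    # two-sided: as or more extreme in either direction around mn/2
    if (abs(u - mn / 2) >= abs(obs - mn / 2) - 1e-9) count <- count + 1
  }
  count / ncol(combos)
}

# standard error of a ratio-of-sums estimator by the delta method
ratio_of_sums_se <- function(num, den) {
  r <- sum(num) / sum(den)
  resid <- num - r * den
  sqrt(length(num) * stats::var(resid)) / sum(den)
}
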