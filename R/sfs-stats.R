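#' Subsample pooled counts to a uniform depth
#'
#' Site-frequency statistics (Tajima's D, Fay & Wu's H) require a common
#' sample size. Sites with depth below `target` are excluded, sites above
#' `max_depth` are excluded as suspect duplications, and the remaining sites
#' have `target` reads drawn without replacement (hypergeometric counts).
#' Deterministic under the caller's seed.
#'
#' @param k minor (or derived) read counts per site.
#' @param depth total read depth per site.
#' @param target uniform sample size to draw (default 30).
#' @param max_depth maximum accepted depth (default 360).
#' @return data.frame with columns `site` (index into the input), `k`
#'   (subsampled count) and `n` (= target).
#' @export
subsample_to_uniform_depth <- function(k, depth, target = 30, max_depth = 360) {
  stopifnot(length(k) == length(depth), all(k <= depth))
  keep <- which(depth >= target & depth <= max_depth)
  if (length(keep) == 0) {
    return(data.frame(site = integer(), k = integer(), n = integer()))
  }
  sub_k <- rhyper(length(keep), m = k[keep], n = depth[keep] - k[keep],
                  k = target)
  data.frame(site = keep, k = sub_k, n = as.integer(target))
}

#' Coefficients of Tajima's D at sample size n
#' @keywords internal
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, e1 = e1, e2 = e2)
}

#' Tajima's D from uniform-depth subsampled counts
#'
#' Classical Tajima's D computed on a window of sites that were subsampled to
#' a common sample size `n`: `D = (theta_pi - theta_W) / sqrt(Vhat)` with
#' `theta_pi = sum 2 k (n - k) / (n (n - 1))`, `theta_W = S / a1`, and the
#' standard variance coefficients at sample size `n`. Alleles whose subsampled
#' count falls below `min_count` are treated as absent (the site becomes
#' monomorphic), a guard against sequencing errors.
#'
#' @param k vector of minor-allele subsampled counts for the window's sites
#'   (monomorphic sites may be included as 0; they contribute nothing).
#' @param n uniform sample size (>= 4).
#' @param min_count minimum subsampled allele count (default 2).
#' @param covered_fraction fraction of the window with usable coverage;
#'   windows under `min_covered_fraction` return NA.
#' @param min_covered_fraction default 0.5.
#' @return Tajima's D, or NA when no polymorphic site remains or coverage is
#'   insufficient.
#' @export
tajimas_d <- function(k, n, min_count = 2, covered_fraction = 1,
                      min_covered_fraction = 0.5) {
  if (n < 4) stop("Tajima's D needs a sample size of at least 4")
  if (covered_fraction < min_covered_fraction) return(NA_real_)
  minor <- pmin(k, n - k)
  k <- k[minor >= min_count]
  s <- length(k)
  if (s == 0) return(NA_real_)
  cst <- tajima_constants(n)
  theta_pi <- sum(2 * k * (n - k)) / (n * (n - 1))
  theta_w <- s / cst$a1
  v <- cst$e1 * s + cst$e2 * s * (s - 1)
  (theta_pi - theta_w) / sqrt(v)
}

#' Polarize a biallelic site against an outgroup base
#'
#' The derived allele is the one not matching the outgroup. Sites where the
#' outgroup base matches neither allele, or is N, cannot be polarized and are
#' skipped (NA).
#'
#' @param allele1,allele2 the two alleles (e.g. major/minor).
#' @param count1,count2 their counts.
#' @param outgroup outgroup base at the site.
#' @return derived-allele count, or NA when the site cannot be polarized.
#'   Vectorized.
#' @export
polarize <- function(allele1, allele2, count1, count2, outgroup) {
  ifelse(outgroup == allele1, count2,
         ifelse(outgroup == allele2, count1, NA_integer_))
}

#' Fay & Wu's H from polarized uniform-depth counts
#'
#' `H = theta_pi - theta_H` with `theta_pi = sum 2 k (n - k) / (n (n - 1))`
#' and `theta_H = sum 2 k^2 / (n (n - 1))`, `k` the derived-allele count at
#' sample size `n`. Strongly negative H indicates an excess of high-frequency
#' derived alleles, the footprint of a recent hard sweep. Sites whose minor
#' allele count is `<= nolowfreq` are excluded entirely (sequencing-error
#' guard mirroring the `-nolowfreq` convention of pooled-data implementations).
#'
#' When `normalized = TRUE` the statistic is divided by the standard deviation
#' estimated from Watterson's theta (the Zeng-style normalization of
#' `theta_pi - theta_L`, using `H = 2 (theta_pi - theta_L)`).
#'
#' @param k derived-allele counts at the window's polarized sites.
#' @param n uniform sample size.
#' @param nolowfreq exclude sites whose minor allele count is <= this value
#'   (default 3).
#' @param normalized divide by the estimated standard deviation
#'   (default FALSE: the raw `theta_pi - theta_H`).
#' @return H, or NA when no usable site remains.
#' @export
fay_wu_h <- function(k, n, nolowfreq = 3, normalized = FALSE) {
  k <- k[!is.na(k)]
  minor <- pmin(k, n - k)
  k <- k[minor > nolowfreq]
  k <- k[k > 0 & k < n]
  if (length(k) == 0) return(NA_real_)
  theta_pi <- sum(2 * k * (n - k)) / (n * (n - 1))
  theta_h <- sum(2 * k^2) / (n * (n - 1))
  h <- theta_pi - theta_h
  if (!normalized) return(h)
  # Var(theta_pi - theta_L); H = 2 (theta_pi - theta_L)
  s <- length(k)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  bn1 <- sum(1 / seq_len(n)^2)
  theta_w <- s / a1
  theta_sq <- s * (s - 1) / (a1^2 + a2)
  v <- theta_w * (n - 2) / (6 * (n - 1)) +
    theta_sq * (18 * n^2 * (3 * n + 2) * bn1 -
                  (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  if (v <= 0) return(NA_real_)
  (h / 2) / sqrt(v)
}

#' Windowed pooled Tajima's D and Fay & Wu's H for one reproductive mode
#'
#' Applies the depth filters and uniform-depth subsampling, polarizes sites
#' against the outgroup where available, and evaluates both statistics per
#' window of `size` bp.
#'
#' @param snps a `snp_table` (typically the unfiltered calls).
#' @param mode `"CP"` or `"OP"`.
#' @param outgroup named `DNAStringSet` aligned to the reference coordinates
#'   (NULL skips Fay & Wu's H).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param size window size in bp (default 1e5), nonoverlapping.
#' @param target,max_depth see [subsample_to_uniform_depth()].
#' @param min_count,min_covered_fraction see [tajimas_d()].
#' @param mincov,maxcov depth bounds applied to sites entering Fay & Wu's H.
#' @param nolowfreq see [fay_wu_h()].
#' @return data.frame: chrom, start, end (0-based half-open), n_snps,
#'   tajimas_d, fay_wu_h.
#' @export
sfs_window_stats <- function(snps, mode, outgroup = NULL, chrom_lengths,
                             size = 1e5, target = 30, max_depth = 360,
                             min_count = 2, min_covered_fraction = 0.5,
                             mincov = 4, maxcov = 180, nolowfreq = 3) {
  mf <- mode_frequencies(snps)
  depth <- mf$depth[, mode]
  minor <- round(mf$p[, mode] * depth)
  sub <- subsample_to_uniform_depth(minor, depth, target, max_depth)

  derived_k <- rep(NA_integer_, nrow(sub))
  if (!is.null(outgroup)) {
    sites <- snps$info[sub$site, , drop = FALSE]
    og <- mapply(function(ch, p) {
      if (!ch %in% names(outgroup)) return("N")
      as.character(Biostrings::subseq(outgroup[[ch]], p, p))
    }, sites$chrom, sites$pos, USE.NAMES = FALSE)
    ok_cov <- depth[sub$site] >= mincov & depth[sub$site] <= maxcov
    derived_k <- polarize(sites$major, sites$minor,
                          sub$n - sub$k, sub$k, og)
    derived_k[!ok_cov] <- NA_integer_
  }

  out <- list()
  for (ch in names(chrom_lengths)) {
    wins <- make_windows(chrom_lengths[[ch]], size, size)
    if (nrow(wins) == 0) next
    on_ch <- snps$info$chrom[sub$site] == ch
    pos0 <- snps$info$pos[sub$site][on_ch] - 1L
    k_ch <- sub$k[on_ch]
    dk_ch <- derived_k[on_ch]
    idx <- findInterval(pos0, wins$start)
    idx[pos0 >= wins$end[pmax(idx, 1)]] <- NA  # beyond last full window
    d_vals <- h_vals <- rep(NA_real_, nrow(wins))
    n_snps <- integer(nrow(wins))
    for (w in seq_len(nrow(wins))) {
      in_w <- which(!is.na(idx) & idx == w)
      n_snps[w] <- length(in_w)
      if (length(in_w) == 0) next
      d_vals[w] <- tajimas_d(k_ch[in_w], target, min_count,
                             covered_fraction = 1,
                             min_covered_fraction = min_covered_fraction)
      if (!is.null(outgroup)) {
        h_vals[w] <- fay_wu_h(dk_ch[in_w], target, nolowfreq)
      }
    }
    out[[ch]] <- data.frame(chrom = ch, start = wins$start, end = wins$end,
                            n_snps = n_snps, tajimas_d = d_vals,
                            fay_wu_h = h_vals, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
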