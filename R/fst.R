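#' Expected heterozygosity of a biallelic site
#'
#' `H_E = 1 - p^2 - (1 - p)^2 = 2 p (1 - p)` from the allele frequency `p`.
#'
#' @param p allele frequency (vectorized).
#' @export
expected_heterozygosity <- function(p) 1 - p^2 - (1 - p)^2

#' Per-SNP F_ST components between two groups of pools
#'
#' Returns the numerator and denominator of the chosen estimator so that
#' multilocus and windowed values can be formed as ratios of sums.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`nei`}{`(H_T - H_S) / H_T` with `H_S` the mean within-group
#'     heterozygosity `2 p_i (1 - p_i)` and `H_T = 2 pbar (1 - pbar)` at the
#'     mean frequency; the plain plug-in estimator, upward-biased at finite
#'     depth.}
#'   \item{`pool_corrected`}{an identity-probability estimator for Pool-seq:
#'     within-group heterozygosities are de-biased for the two-stage sampling
#'     of a finite pool of `n` chromosomes read at depth `d` (each observed
#'     `2 p (1 - p)` is inflated by `d/(d-1) * n/(n-1)`, removing the `1/d`
#'     and `1/n` identity terms), and the total heterozygosity is recomposed
#'     on the Nei scale as `(H_S + pi_between) / 2` with
#'     `pi_between = p1 (1 - p2) + p2 (1 - p1)` (unbiased across independent
#'     pools). It converges to the Nei estimator as `d, n -> Inf` and may go
#'     slightly negative at undifferentiated SNPs, the price of unbiasedness.}
#' }
#'
#' @param p1,p2 minor (or derived) allele frequencies in the two groups.
#' @param d1,d2 read depths (required for `pool_corrected`).
#' @param n1,n2 pool sizes in chromosomes (`2 * lineages`).
#' @param estimator `"pool_corrected"` (default) or `"nei"`.
#' @return list with vectors `num`, `den`, and `fst = num/den` (NA where the
#'   denominator is 0 or a depth is 0).
#' @export
fst_components <- function(p1, p2, d1 = NULL, d2 = NULL, n1 = NULL, n2 = NULL,
                           estimator = c("pool_corrected", "nei")) {
  estimator <- match.arg(estimator)
  if (estimator == "nei") {
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    num <- ht - hs
    den <- ht
  } else {
    if (is.null(d1) || is.null(d2) || is.null(n1) || is.null(n2)) {
      stop("pool_corrected estimator needs depths d1, d2 and pool sizes n1, n2")
    }
    bad <- d1 < 1 | d2 < 1
    corr1 <- d1 / pmax(d1 - 1, 1) * n1 / (n1 - 1)
    corr2 <- d2 / pmax(d2 - 1, 1) * n2 / (n2 - 1)
    h1 <- 2 * p1 * (1 - p1) * corr1
    h2 <- 2 * p2 * (1 - p2) * corr2
    hs <- (h1 + h2) / 2
    pib <- p1 * (1 - p2) + p2 * (1 - p1)
    ht <- (hs + pib) / 2
    num <- ht - hs
    den <- ht
    num[bad] <- NA_real_
    den[bad] <- NA_real_
  }
  fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
  list(num = num, den = den, fst = fst)
}

#' Per-SNP F_ST between two groups
#'
#' @inheritParams fst_components
#' @return vector of per-SNP F_ST values (NA where undefined).
#' @export
fst_snp <- function(p1, p2, d1 = NULL, d2 = NULL, n1 = NULL, n2 = NULL,
                    estimator = c("pool_corrected", "nei")) {
  fst_components(p1, p2, d1, d2, n1, n2, estimator)$fst
}

#' Multilocus F_ST as a ratio of sums
#'
#' Sums the per-SNP numerators and denominators before taking the ratio
#' (never a mean of per-SNP ratios), the standard way to combine loci.
#'
#' @inheritParams fst_components
#' @export
fst_multilocus <- function(p1, p2, d1 = NULL, d2 = NULL, n1 = NULL, n2 = NULL,
                           estimator = c("pool_corrected", "nei")) {
  comp <- fst_components(p1, p2, d1, d2, n1, n2, estimator)
  ok <- !is.na(comp$num) & !is.na(comp$den)
  sum(comp$num[ok]) / sum(comp$den[ok])
}

#' Between-mode F_ST of a SNP table
#'
#' Convenience wrapper: pools the SNP table by reproductive mode
#' ([mode_frequencies()]) and returns per-SNP components plus the multilocus
#' ratio-of-sums value.
#'
#' @param snps a `snp_table`.
#' @param estimator see [fst_components()].
#' @return list with `snp` (data.frame chrom, pos, fst, num, den) and
#'   `multilocus` (scalar).
#' @export
fst_by_mode <- function(snps, estimator = c("pool_corrected", "nei")) {
  estimator <- match.arg(estimator)
  mf <- mode_frequencies(snps)
  comp <- fst_components(mf$p[, "CP"], mf$p[, "OP"],
                         mf$depth[, "CP"], mf$depth[, "OP"],
                         mf$pool_size["CP"], mf$pool_size["OP"],
                         estimator)
  ok <- !is.na(comp$num) & !is.na(comp$den)
  list(snp = data.frame(chrom = snps$info$chrom, pos = snps$info$pos,
                        fst = comp$fst, num = comp$num, den = comp$den,
                        stringsAsFactors = FALSE),
       multilocus = sum(comp$num[ok]) / sum(comp$den[ok]))
}
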