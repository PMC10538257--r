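new_snp_table <- function(info, major_counts, minor_counts, populations) {
  stopifnot(nrow(info) == nrow(major_counts),
            all(dim(major_counts) == dim(minor_counts)))
  structure(list(info = info,
                 major_counts = major_counts,
                 minor_counts = minor_counts,
                 populations = populations),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d biallelic SNPs x %d populations\n",
              nrow(x$info), ncol(x$major_counts)))
  invisible(x)
}

#' Subset a SNP table by row index or logical mask
#' @export
subset_snps <- function(snps, keep) {
  new_snp_table(snps$info[keep, , drop = FALSE],
                snps$major_counts[keep, , drop = FALSE],
                snps$minor_counts[keep, , drop = FALSE],
                snps$populations)
}

#' Per-population read depth of a SNP table (major + minor counts)
#' @export
snp_depth <- function(snps) snps$major_counts + snps$minor_counts

#' Identify biallelic SNPs from population-level pooled counts
#'
#' A position is a SNP when at least two nucleotide alleles are observed over
#' all populations and the global minor allele count reaches `mac_min`
#' (default 4 reads). Triallelic positions whose third allele carries exactly
#' one read are treated as sequencing noise: the third allele is ignored and
#' the position kept as biallelic. Positions whose third allele carries two or
#' more reads are dropped. N and deletion counts never enter allele counts or
#' depth.
#'
#' @param sync a population-level `pool_sync` (see
#'   [merge_replicate_libraries()]).
#' @param mac_min minimum global minor allele count.
#' @return a `snp_table`: `$info` (chrom, pos, ref, major, minor, maf with MAF
#'   computed from counts summed over all populations), `$major_counts` /
#'   `$minor_counts` (sites x populations), `$populations`.
#' @export
call_snps <- function(sync, mac_min = 4) {
  nuc <- sync$counts[, 1:4, , drop = FALSE]  # A,T,C,G only
  n_sites <- dim(nuc)[1]
  if (n_sites == 0) {
    return(new_snp_table(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 major = character(), minor = character(), maf = numeric()),
      matrix(0L, 0, dim(nuc)[3]), matrix(0L, 0, dim(nuc)[3]),
      attr(sync, "populations")))
  }
  global <- rowSums(nuc, dims = 2)                     # sites x 4
  ord <- t(apply(global, 1, order, decreasing = TRUE)) # allele rank per site
  sorted <- t(vapply(seq_len(n_sites),
                     function(i) global[i, ord[i, ]], numeric(4)))
  c2 <- sorted[, 2]
  c3 <- sorted[, 3]
  keep <- c2 >= mac_min & c3 <= 1
  major_i <- ord[, 1]
  minor_i <- ord[, 2]
  bases <- SYNC_BASES[1:4]
  idx <- which(keep)
  n_pop <- dim(nuc)[3]
  major_counts <- minor_counts <- matrix(0L, length(idx), n_pop)
  for (j in seq_len(n_pop)) {
    slab <- nuc[idx, , j, drop = FALSE]
    dim(slab) <- c(length(idx), 4)
    major_counts[, j] <- slab[cbind(seq_along(idx), major_i[idx])]
    minor_counts[, j] <- slab[cbind(seq_along(idx), minor_i[idx])]
  }
  maf <- sorted[idx, 2] / (sorted[idx, 1] + sorted[idx, 2])
  info <- data.frame(chrom = sync$sites$chrom[idx],
                     pos = sync$sites$pos[idx],
                     ref = sync$sites$ref[idx],
                     major = bases[major_i[idx]],
                     minor = bases[minor_i[idx]],
                     maf = maf,
                     stringsAsFactors = FALSE)
  pops <- attr(sync, "populations")
  new_snp_table(info, major_counts, minor_counts, pops)
}

#' Depth and minor-allele-frequency filtering of called SNPs
#'
#' Keeps SNPs whose per-population depth lies within `[depth_min, depth_max]`
#' in every population (bounds inclusive) and whose global minor allele
#' frequency is at least `maf_min`. The depth window discards positions with
#' unreliable frequency estimates (low depth) or likely collapsed duplications
#' (high depth); the MAF floor removes rare alleles uninformative for an
#' F_ST-based scan.
#'
#' @param snps a `snp_table` from [call_snps()].
#' @param depth_min,depth_max inclusive per-population depth bounds.
#' @param maf_min inclusive global minor-allele-frequency floor.
#' @return the filtered `snp_table`.
#' @export
filter_snps <- function(snps, depth_min = 20, depth_max = 60, maf_min = 0.05) {
  depth <- snp_depth(snps)
  ok_depth <- rowSums(depth >= depth_min & depth <= depth_max) == ncol(depth)
  keep <- ok_depth & snps$info$maf >= maf_min
  subset_snps(snps, keep)
}

#' Mode-level allele counts of a SNP table
#'
#' Sums major/minor counts over the populations of each reproductive mode and
#' returns frequencies, depths, and pool sizes (chromosomes) per mode.
#'
#' @param snps a `snp_table` whose `$populations` carries `mode` and
#'   `n_lineages`.
#' @return a list with elements `p` (minor-allele frequency matrix, columns CP
#'   and OP), `depth` (same shape) and `pool_size` (named vector, number of
#'   chromosomes per mode).
#' @export
mode_frequencies <- function(snps) {
  pops <- snps$populations
  if (is.null(pops)) stop("snp_table lacks population metadata")
  out_p <- out_d <- matrix(NA_real_, nrow(snps$info), 2,
                           dimnames = list(NULL, c("CP", "OP")))
  pool_size <- c(CP = 0L, OP = 0L)
  for (m in c("CP", "OP")) {
    j <- which(pops$mode == m)
    minor <- rowSums(snps$minor_counts[, j, drop = FALSE])
    major <- rowSums(snps$major_counts[, j, drop = FALSE])
    out_d[, m] <- major + minor
    out_p[, m] <- ifelse(out_d[, m] > 0, minor / out_d[, m], NA_real_)
    pool_size[m] <- 2L * sum(pops$n_lineages[j])
  }
  list(p = out_p, depth = out_d, pool_size = pool_size)
}
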