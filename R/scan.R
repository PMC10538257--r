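#' Build windows over a chromosome
#'
#' Window starts are `0, step, 2*step, ...` and only windows lying fully
#' inside the chromosome are returned. `step = size` gives contiguous
#' nonoverlapping windows; `step < size` gives a sliding set.
#'
#' @param chrom_length chromosome length in bp.
#' @param size window size in bp.
#' @param step step between window starts (default `size`).
#' @return data.frame with 0-based half-open `start`, `end`.
#' @export
make_windows <- function(chrom_length, size, step = size) {
  if (size > chrom_length) {
    return(data.frame(start = integer(), end = integer()))
  }
  starts <- seq.int(0L, chrom_length - size, by = step)
  data.frame(start = as.integer(starts), end = as.integer(starts + size))
}

#' Windowed F_ST from per-SNP components
#'
#' Window F_ST is the ratio of summed per-SNP numerators to summed
#' denominators over the SNPs falling in each window (never a mean of
#' per-SNP ratios).
#'
#' @param snp_fst data.frame with `chrom`, `pos` (1-based), `num`, `den`
#'   (from [fst_by_mode()]).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param size,step window geometry in bp (e.g. 20000 / 5000 for a sliding
#'   scan, 1e5 / 1e5 for contiguous windows).
#' @return data.frame: chrom, start, end (0-based half-open), n_snps, fst.
#' @export
fst_windows <- function(snp_fst, chrom_lengths, size = 20000, step = 5000) {
  out <- lapply(names(chrom_lengths), function(ch) {
    wins <- make_windows(chrom_lengths[[ch]], size, step)
    if (nrow(wins) == 0) return(NULL)
    rows <- snp_fst[snp_fst$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = rows$pos, width = 1L),
      IRanges::IRanges(start = wins$start + 1L, end = wins$end))
    qi <- S4Vectors::queryHits(hits)
    wi <- S4Vectors::subjectHits(hits)
    num <- tapply(rows$num[qi], factor(wi, levels = seq_len(nrow(wins))),
                  sum, na.rm = TRUE)
    den <- tapply(rows$den[qi], factor(wi, levels = seq_len(nrow(wins))),
                  sum, na.rm = TRUE)
    n_snps <- tabulate(wi, nbins = nrow(wins))
    fst <- ifelse(!is.na(den) & den > 0, num / den, NA_real_)
    data.frame(chrom = ch, start = wins$start, end = wins$end,
               n_snps = n_snps, fst = as.numeric(fst),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Windowed expected heterozygosity per reproductive mode
#'
#' @param snps a filtered `snp_table`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param size nonoverlapping window size (default 1e5).
#' @return data.frame: chrom, start, end, n_snps, he_cp, he_op (mean per-SNP
#'   H_E of the window).
#' @export
he_windows <- function(snps, chrom_lengths, size = 1e5) {
  mf <- mode_frequencies(snps)
  he <- expected_heterozygosity(mf$p)
  out <- lapply(names(chrom_lengths), function(ch) {
    wins <- make_windows(chrom_lengths[[ch]], size, size)
    if (nrow(wins) == 0) return(NULL)
    on_ch <- snps$info$chrom == ch
    pos0 <- snps$info$pos[on_ch] - 1L
    idx <- findInterval(pos0, wins$start)
    idx[idx >= 1 & pos0 >= wins$end[pmax(idx, 1)]] <- NA
    f <- factor(idx, levels = seq_len(nrow(wins)))
    data.frame(chrom = ch, start = wins$start, end = wins$end,
               n_snps = as.integer(table(f)),
               he_cp = as.numeric(tapply(he[on_ch, "CP"], f, mean)),
               he_op = as.numeric(tapply(he[on_ch, "OP"], f, mean)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Delimit candidate regions from an F_ST window scan
#'
#' Maximal runs of overlapping (or adjacent) windows whose F_ST reaches
#' `fst_threshold` are merged into regions. If a table of per-SNP association
#' scores is supplied (e.g. an externally computed contrast statistic), a
#' region is confirmed only when it contains at least `min_assoc` SNPs with a
#' score above `assoc_threshold`. If per-SNP F_ST values are supplied, region
#' boundaries are trimmed to the outermost SNPs with F_ST above
#' `trim_fst` (default 0.5), a reproducible surrogate for a manual call.
#'
#' Windows with NA F_ST are ignored; the result does not depend on the input
#' window order.
#'
#' @param windows data.frame from [fst_windows()] (chrom, start, end, fst,
#'   optionally n_snps).
#' @param snp_fst optional per-SNP F_ST data.frame (chrom, pos, fst).
#' @param assoc optional per-SNP association scores (chrom, pos, score).
#' @param fst_threshold window mean F_ST needed to seed a region
#'   (default 0.25).
#' @param assoc_threshold score above which a SNP counts as associated.
#' @param min_assoc minimum number of associated SNPs to confirm a region.
#' @param trim_fst per-SNP F_ST used for boundary trimming.
#' @return data.frame of candidate regions: chrom, start, end (0-based
#'   half-open), mean_fst (mean F_ST over member windows), n_assoc (NA when no
#'   scores given).
#' @export
delimit_candidate_region <- function(windows, snp_fst = NULL, assoc = NULL,
                                     fst_threshold = 0.25,
                                     assoc_threshold = 60, min_assoc = 1,
                                     trim_fst = 0.5) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_fst = numeric(), n_assoc = integer(),
                      stringsAsFactors = FALSE)
  w <- windows[!is.na(windows$fst) & windows$fst >= fst_threshold, ,
               drop = FALSE]
  if (nrow(w) == 0) return(empty)
  w <- w[order(w$chrom, w$start), , drop = FALSE]
  regions <- list()
  for (ch in unique(w$chrom)) {
    wc <- w[w$chrom == ch, , drop = FALSE]
    run_start <- wc$start[1]
    run_end <- wc$end[1]
    members <- wc$fst[1]
    flush <- function() {
      regions[[length(regions) + 1]] <<- data.frame(
        chrom = ch, start = run_start, end = run_end,
        mean_fst = mean(members), stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(wc))[-1]) {
      if (wc$start[i] <= run_end) {
        run_end <- max(run_end, wc$end[i])
        members <- c(members, wc$fst[i])
      } else {
        flush()
        run_start <- wc$start[i]
        run_end <- wc$end[i]
        members <- wc$fst[i]
      }
    }
    flush()
  }
  regions <- do.call(rbind, regions)

  if (!is.null(assoc)) {
    regions$n_assoc <- vapply(seq_len(nrow(regions)), function(i) {
      sum(assoc$chrom == regions$chrom[i] &
            (assoc$pos - 1L) >= regions$start[i] &
            (assoc$pos - 1L) < regions$end[i] &
            assoc$score > assoc_threshold)
    }, integer(1))
    regions <- regions[regions$n_assoc >= min_assoc, , drop = FALSE]
  } else {
    regions$n_assoc <- NA_integer_
  }
  if (nrow(regions) == 0) return(empty)

  if (!is.null(snp_fst)) {
    for (i in seq_len(nrow(regions))) {
      inside <- snp_fst$chrom == regions$chrom[i] &
        (snp_fst$pos - 1L) >= regions$start[i] &
        (snp_fst$pos - 1L) < regions$end[i]
      high <- inside & !is.na(snp_fst$fst) & snp_fst$fst > trim_fst
      if (any(high)) {
        regions$start[i] <- min(snp_fst$pos[high]) - 1L
        regions$end[i] <- max(snp_fst$pos[high])
      }
    }
  }
  rownames(regions) <- NULL
  regions
}

#' Normalized sequencing-depth ratio scan
#'
#' For detecting copy-number differences between the two modes: each mode's
#' per-position depth is first normalized by that mode's genome-wide mean
#' depth, then the per-position ratio `OP / (OP + CP)` is averaged over
#' nonoverlapping windows. Segments with equal copy number in both modes have
#' an expected ratio of 0.5; a segment deleted from one OP copy (half copy
#' number) has expectation 1/3.
#'
#' @param depth_op,depth_cp per-position depth vectors of the scanned
#'   interval, one value per bp.
#' @param window window size in bp (default 2000).
#' @param norm_op,norm_cp normalization constants (genome-wide mean depth per
#'   mode); default the means of the supplied tracks.
#' @param offset 0-based genomic offset of the first position.
#' @return data.frame: start, end (0-based half-open), ratio (NA for windows
#'   where both normalized depths are 0).
#' @export
depth_ratio_scan <- function(depth_op, depth_cp, window = 2000,
                             norm_op = mean(depth_op),
                             norm_cp = mean(depth_cp), offset = 0L) {
  stopifnot(length(depth_op) == length(depth_cp))
  op <- depth_op / norm_op
  cp <- depth_cp / norm_cp
  tot <- op + cp
  ratio <- ifelse(tot > 0, op / tot, NA_real_)
  wins <- make_windows(length(ratio), window, window)
  if (nrow(wins) == 0) {
    return(data.frame(start = integer(), end = integer(), ratio = numeric()))
  }
  idx <- rep(seq_len(nrow(wins)), each = window)
  vals <- ratio[seq_len(nrow(wins) * window)]
  data.frame(start = wins$start + offset, end = wins$end + offset,
             ratio = as.numeric(tapply(vals, idx, mean, na.rm = TRUE)))
}

#' Compare window statistics inside a candidate region against the rest
#'
#' Two-sided Mann-Whitney test (exact for small samples, normal approximation
#' otherwise, as in `stats::wilcox.test`) of the window values falling inside
#' the region versus all other windows.
#'
#' @param windows data.frame with chrom, start, end and a `value` column name
#'   given by `stat`.
#' @param region one-row data.frame (chrom, start, end), 0-based half-open.
#' @param stat name of the value column.
#' @return list: `U` statistic, `p_value`, `median_in`, `median_out`, `n_in`,
#'   `n_out`.
#' @export
compare_candidate_vs_rest <- function(windows, region, stat = "fst") {
  v <- windows[[stat]]
  inside <- windows$chrom == region$chrom &
    windows$start < region$end & windows$end > region$start
  x <- v[inside & !is.na(v)]
  y <- v[!inside & !is.na(v)]
  if (length(x) == 0 || length(y) == 0) {
    stop("no usable windows on one side of the comparison")
  }
  if (length(unique(c(x, y))) == 1) {
    # fully tied data: no evidence of a shift in either direction
    return(list(U = length(x) * length(y) / 2, p_value = 1,
                median_in = median(x), median_out = median(y),
                n_in = length(x), n_out = length(y)))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       median_in = median(x), median_out = median(y),
       n_in = length(x), n_out = length(y))
}

#' Paired two-sided Wilcoxon comparison of window values between modes
#'
#' Genome-wide comparison of a per-window statistic measured in both modes
#' over the same windows (signed-rank test).
#'
#' @param x,y per-window values for the two modes (same windows, same order).
#' @return list: `W` statistic, `p_value`, `median_x`, `median_y`.
#' @export
compare_modes_paired <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  wt <- suppressWarnings(wilcox.test(x[ok], y[ok], paired = TRUE,
                                     alternative = "two.sided"))
  list(W = unname(wt$statistic), p_value = wt$p.value,
       median_x = median(x[ok]), median_y = median(y[ok]))
}
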