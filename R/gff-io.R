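#' Read CDS gene models from a GFF3 file
#'
#' Imports gene / mRNA / CDS features and keeps, for every gene, its longest
#' transcript (by summed CDS length), the convention used throughout the
#' per-gene analyses. CDS intervals are converted to 0-based half-open
#' coordinates internally; translation order and frame follow the strand and
#' the GFF phase of the first coding segment.
#'
#' Genes whose CDS length is not a multiple of three after phase adjustment
#' are flagged unusable (`usable = FALSE`) and skipped by downstream coding
#' analyses, with a warning here.
#'
#' @param path GFF3 file.
#' @return an object of class `gene_models`: a list of gene records, each with
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `cds` (data.frame with
#'   0-based half-open `start`, `end`, sorted by genomic position), `phase`
#'   (of the first coding segment in translation order) and `usable`.
#' @export
read_gff_cds <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)

  first_parent <- function(p) {
    vapply(p, function(x) if (length(x) == 0) NA_character_ else x[[1]],
           character(1))
  }
  tx <- gr[type == "mRNA"]
  tx_gene <- setNames(first_parent(S4Vectors::mcols(tx)$Parent),
                      S4Vectors::mcols(tx)$ID)

  cds <- gr[type == "CDS"]
  if (length(cds) == 0) stop("no CDS features in ", path)
  cds_tx <- first_parent(S4Vectors::mcols(cds)$Parent)
  cds_df <- data.frame(
    tx = cds_tx,
    chrom = as.character(GenomicRanges::seqnames(cds)),
    start = GenomicRanges::start(cds) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(cds),
    strand = as.character(GenomicRanges::strand(cds)),
    phase = as.integer(S4Vectors::mcols(cds)$phase),
    stringsAsFactors = FALSE)
  cds_df$phase[is.na(cds_df$phase)] <- 0L

  # longest transcript per gene by summed CDS length
  tx_len <- tapply(cds_df$end - cds_df$start, cds_df$tx, sum)
  genes_of_tx <- tx_gene[names(tx_len)]
  genes_of_tx[is.na(genes_of_tx)] <- names(tx_len)[is.na(genes_of_tx)]
  keep_tx <- tapply(seq_along(tx_len), genes_of_tx, function(i) {
    names(tx_len)[i][which.max(tx_len[i])]
  })

  models <- lapply(names(keep_tx), function(g) {
    t_id <- keep_tx[[g]]
    rows <- cds_df[cds_df$tx == t_id, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    strand <- rows$strand[1]
    phase <- if (strand == "-") rows$phase[nrow(rows)] else rows$phase[1]
    len <- sum(rows$end - rows$start) - phase
    usable <- len %% 3L == 0L && len >= 3L
    if (!usable) {
      warning(sprintf("gene %s: CDS length %d not a multiple of 3; flagged unusable",
                      g, len), call. = FALSE)
    }
    list(gene_id = g, transcript_id = t_id, chrom = rows$chrom[1],
         strand = strand,
         cds = rows[, c("start", "end"), drop = FALSE],
         phase = phase, usable = usable)
  })
  names(models) <- names(keep_tx)
  structure(models, class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d usable)\n", length(x),
              sum(vapply(x, `[[`, logical(1), "usable"))))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff_cds()] for simulated gene models: emits gene, mRNA and
#' CDS features with 1-based inclusive coordinates and per-segment phase.
#'
#' @param models a `gene_models` object.
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (g in models) {
    cds <- g$cds[order(g$cds$start), , drop = FALSE]
    gstart <- min(cds$start) + 1L
    gend <- max(cds$end)
    lines <- c(lines,
      sprintf("%s\tpoolscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, gstart, gend, g$strand, g$gene_id),
      sprintf("%s\tpoolscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, gstart, gend, g$strand, g$transcript_id, g$gene_id))
    # phase per segment in translation order
    ord <- if (g$strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
    phase <- integer(nrow(cds))
    carried <- g$phase
    for (i in ord) {
      phase[i] <- carried
      seg_len <- cds$end[i] - cds$start[i]
      carried <- (3L - ((seg_len - carried) %% 3L)) %% 3L
    }
    for (i in seq_len(nrow(cds))) {
      lines <- c(lines,
        sprintf("%s\tpoolscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                g$chrom, cds$start[i] + 1L, cds$end[i], g$strand, phase[i],
                g$transcript_id, g$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Spliced CDS sequence of a gene model
#'
#' @param gene one element of a `gene_models` list.
#' @param genome a named `DNAStringSet`.
#' @return a `DNAString` in translation order (reverse-complemented for minus
#'   strand genes), with the leading `phase` bases trimmed.
#' @export
cds_sequence <- function(gene, genome) {
  chrom_seq <- genome[[gene$chrom]]
  parts <- lapply(seq_len(nrow(gene$cds)), function(i) {
    Biostrings::subseq(chrom_seq, start = gene$cds$start[i] + 1L,
                       end = gene$cds$end[i])
  })
  s <- do.call(Biostrings::xscat, parts)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  if (gene$phase > 0) s <- Biostrings::subseq(s, start = gene$phase + 1L)
  s
}
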