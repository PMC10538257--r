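EFFECT_IMPACT <- c(
  frameshift = "high", stop_gained = "high", stop_lost = "high",
  missense = "moderate", inframe_deletion = "moderate",
  inframe_insertion = "moderate",
  synonymous = "low",
  intronic = "modifier", intergenic = "modifier",
  splice_adjacent = "modifier", broken_frame = "modifier")

#' Select highly differentiated, well-covered candidate variants
#'
#' The variants carried into effect classification are those with F_ST
#' strictly above `fst_min` (default 0.5, i.e. very different allele
#' frequencies between the modes) and a depth of at least `depth_min` in every
#' population.
#'
#' @param variants data.frame with at least `fst` and the columns named in
#'   `depth_cols` (per-population depths).
#' @param depth_cols names of the per-population depth columns; default all
#'   columns starting with `"depth"`.
#' @param fst_min strict lower bound on F_ST.
#' @param depth_min inclusive per-population depth floor.
#' @return the filtered data.frame.
#' @export
select_candidate_variants <- function(variants, depth_cols = NULL,
                                      fst_min = 0.5, depth_min = 20) {
  if (is.null(depth_cols)) {
    depth_cols <- grep("^depth", names(variants), value = TRUE)
  }
  if (length(depth_cols) == 0) stop("no per-population depth columns found")
  d <- as.matrix(variants[, depth_cols, drop = FALSE])
  keep <- !is.na(variants$fst) & variants$fst > fst_min &
    rowSums(d >= depth_min) == ncol(d)
  variants[keep, , drop = FALSE]
}

# 1-based CDS coordinate (in translation order) of a genomic position, or NA
# if the position is not coding in this gene.
genomic_to_cds <- function(gene, pos) {
  cds <- gene$cds[order(gene$cds$start), , drop = FALSE]
  pos0 <- pos - 1L
  hit <- which(cds$start <= pos0 & pos0 < cds$end)
  if (length(hit) == 0) return(NA_integer_)
  if (gene$strand == "+") {
    before <- if (hit > 1) sum(cds$end[seq_len(hit - 1)] - cds$start[seq_len(hit - 1)]) else 0L
    idx <- before + (pos0 - cds$start[hit]) + 1L
  } else {
    after <- if (hit < nrow(cds)) {
      sum(cds$end[seq(hit + 1, nrow(cds))] - cds$start[seq(hit + 1, nrow(cds))])
    } else 0L
    idx <- after + (cds$end[hit] - pos0 - 1L) + 1L
  }
  idx <- idx - gene$phase
  if (idx < 1) return(NA_integer_)
  as.integer(idx)
}

find_gene_at <- function(genes, chrom, pos) {
  pos0 <- pos - 1L
  for (g in genes) {
    if (g$chrom != chrom) next
    if (pos0 >= min(g$cds$start) && pos0 < max(g$cds$end)) return(g)
  }
  NULL
}

#' Classify the coding effect of a variant
#'
#' SNPs falling in a CDS are translated on the gene's strand and frame and
#' classified as `synonymous`, `missense`, `stop_gained` or `stop_lost`;
#' indels inside a CDS are `inframe_deletion` / `inframe_insertion` when their
#' length is a multiple of three and `frameshift` otherwise. Positions inside
#' a gene but outside its CDS are `intronic` (`splice_adjacent` within 2 bp of
#' an exon boundary); everything else is `intergenic`. Genes flagged unusable
#' (broken reading frame) yield `broken_frame` with a warning.
#'
#' @param chrom,pos variant position (1-based).
#' @param ref,alt reference and alternative alleles on the plus strand; an
#'   indel is encoded VCF-style, e.g. ref "CAT" alt "C" (deletion) or ref "C"
#'   alt "CAT" (insertion), anchored at `pos`.
#' @param genes a `gene_models` object.
#' @param genome named `DNAStringSet`; the reference base(s) at `pos` must
#'   equal `ref`.
#' @return one-row data.frame: gene (NA if intergenic), effect, codon_change,
#'   aa_change, impact.
#' @export
classify_variant <- function(chrom, pos, ref, alt, genes, genome) {
  genome_ref <- as.character(Biostrings::subseq(genome[[chrom]], pos,
                                                pos + nchar(ref) - 1L))
  if (genome_ref != ref) {
    stop(sprintf("reference mismatch at %s:%d: genome has '%s', variant claims '%s'",
                 chrom, pos, genome_ref, ref))
  }
  result <- function(gene, effect, codon_change = NA_character_,
                     aa_change = NA_character_) {
    data.frame(gene = if (is.null(gene)) NA_character_ else gene$gene_id,
               effect = effect, codon_change = codon_change,
               aa_change = aa_change, impact = unname(EFFECT_IMPACT[effect]),
               stringsAsFactors = FALSE)
  }
  gene <- find_gene_at(genes, chrom, pos)
  if (is.null(gene)) return(result(NULL, "intergenic"))
  if (!gene$usable) {
    warning(sprintf("gene %s has a broken reading frame; variant at %s:%d classified as modifier",
                    gene$gene_id, chrom, pos), call. = FALSE)
    return(result(gene, "broken_frame"))
  }

  is_indel <- nchar(ref) != nchar(alt)
  if (is_indel) {
    # the changed bases sit after the anchor base
    span <- max(nchar(ref), nchar(alt))
    touched <- (pos + 1L):(pos + span - 1L)
    in_cds <- any(vapply(touched, function(p) !is.na(genomic_to_cds(gene, p)),
                         logical(1)))
    if (!in_cds) {
      return(result(gene, intron_effect(gene, pos)))
    }
    indel_len <- abs(nchar(ref) - nchar(alt))
    if (indel_len %% 3L == 0L) {
      eff <- if (nchar(ref) > nchar(alt)) "inframe_deletion" else "inframe_insertion"
      return(result(gene, eff))
    }
    return(result(gene, "frameshift"))
  }

  cds_pos <- genomic_to_cds(gene, pos)
  if (is.na(cds_pos)) return(result(gene, intron_effect(gene, pos)))
  cds <- cds_sequence(gene, genome)
  codon_i <- (cds_pos - 1L) %/% 3L + 1L
  within <- (cds_pos - 1L) %% 3L + 1L
  old_codon <- as.character(Biostrings::subseq(cds, (codon_i - 1L) * 3L + 1L,
                                               codon_i * 3L))
  base <- if (gene$strand == "+") alt else {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(alt)))
  }
  new_codon <- old_codon
  substr(new_codon, within, within) <- base
  old_aa <- translate_codon(old_codon)
  new_aa <- translate_codon(new_codon)
  effect <- if (old_aa == new_aa) "synonymous"
    else if (new_aa == "*") "stop_gained"
    else if (old_aa == "*") "stop_lost"
    else "missense"
  result(gene, effect,
         codon_change = paste0(old_codon, ">", new_codon),
         aa_change = paste0(old_aa, codon_i, new_aa))
}

intron_effect <- function(gene, pos) {
  pos0 <- pos - 1L
  near_boundary <- any(abs(gene$cds$start - pos0) <= 2L |
                         abs(gene$cds$end - pos0) <= 2L)
  if (nrow(gene$cds) > 1 && near_boundary) "splice_adjacent" else "intronic"
}

#' Classify a table of variants
#'
#' Vectorized driver over [classify_variant()].
#'
#' @param variants data.frame with chrom, pos, ref, alt.
#' @inheritParams classify_variant
#' @return the input with gene, effect, codon_change, aa_change, impact
#'   columns appended.
#' @export
classify_variants <- function(variants, genes, genome) {
  calls <- lapply(seq_len(nrow(variants)), function(i) {
    classify_variant(variants$chrom[i], variants$pos[i], variants$ref[i],
                     variants$alt[i], genes, genome)
  })
  cbind(variants, do.call(rbind, calls))
}

#' Per-gene effect counts and callable coverage
#'
#' Summarizes, gene by gene, the counts of high-differentiation variants per
#' effect category and the percentage of the gene span whose depth reaches
#' `depth_min` in every population of each mode.
#'
#' @param effects output of [classify_variants()] on the selected candidate
#'   variants.
#' @param genes a `gene_models` object.
#' @param depth_cp,depth_op per-position depth matrices (positions x
#'   populations of the mode) covering `coords`; a position is callable for a
#'   mode only when every population of that mode reaches `depth_min`.
#' @param coords 1-based genomic positions of the depth matrix rows (single
#'   chromosome).
#' @param chrom chromosome of the depth track.
#' @param depth_min callable threshold (default 20).
#' @return data.frame with one row per gene: gene, counts of nonsense
#'   (stop_gained), frameshift, missense, inframe variants, and `pct_cp` /
#'   `pct_op` coverage percentages (NA for genes outside the depth track).
#' @export
per_gene_summary <- function(effects, genes, depth_cp = NULL, depth_op = NULL,
                             coords = NULL, chrom = NULL, depth_min = 20) {
  count_eff <- function(gid, eff) {
    sum(!is.na(effects$gene) & effects$gene == gid & effects$effect %in% eff)
  }
  rows <- lapply(genes, function(g) {
    pct_cp <- pct_op <- NA_real_
    if (!is.null(depth_cp) && !is.null(coords) && identical(g$chrom, chrom)) {
      span <- seq.int(min(g$cds$start) + 1L, max(g$cds$end))
      i <- match(span, coords)
      ok <- !is.na(i)
      if (any(ok)) {
        call_cp <- rowSums(depth_cp[i[ok], , drop = FALSE] >= depth_min) ==
          ncol(depth_cp)
        call_op <- rowSums(depth_op[i[ok], , drop = FALSE] >= depth_min) ==
          ncol(depth_op)
        pct_cp <- 100 * sum(call_cp) / length(span)
        pct_op <- 100 * sum(call_op) / length(span)
      }
    }
    data.frame(gene = g$gene_id,
               nonsense = count_eff(g$gene_id, "stop_gained"),
               frameshift = count_eff(g$gene_id, "frameshift"),
               missense = count_eff(g$gene_id, "missense"),
               inframe = count_eff(g$gene_id,
                                   c("inframe_deletion", "inframe_insertion")),
               pct_cp = pct_cp, pct_op = pct_op,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
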