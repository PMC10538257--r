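#' Configuration of the synthetic Pool-seq truth
#'
#' Describes the ground-truth allele-frequency landscape the generator draws:
#' a small multi-chromosome genome, three populations per reproductive mode
#' (CP, cyclical parthenogens; OP, obligate parthenogens) sequenced as pools
#' of clonal lineages with two replicate libraries each, a neutral background
#' with low between-mode differentiation, and one candidate interval where the
#' modes are strongly differentiated and OP diversity is reduced.
#'
#' Defaults emulate the study design the package targets: pools of 20--21 (CP)
#' and 14 (OP) lineages, ~15--20x depth per library, background between-mode
#' F_ST of 0.025, candidate F_ST of 0.35 with OP expected heterozygosity 0.14,
#' and an outgroup diverged 1% at the nucleotide level. The genome itself is
#' kept at desk scale (4 x 2 Mb, 200-kb candidate interval on the last
#' chromosome, named "X").
#'
#' @param n_chromosomes,chrom_length genome shape (all chromosomes share one
#'   length, in bp).
#' @param n_pops_per_mode populations per reproductive mode.
#' @param lineages_cp,lineages_op clonal lineages per pool, recycled to
#'   `n_pops_per_mode`; pool size in chromosomes is `2 * lineages`.
#' @param mean_depth_per_library expected sequencing depth of each library.
#' @param candidate_interval `list(chrom =, start =, end =)`, 0-based
#'   half-open.
#' @param background_fst,candidate_fst expected per-site Nei F_ST between the
#'   two modes outside/inside the candidate interval.
#' @param candidate_he_op expected heterozygosity of OP pools at candidate
#'   sites (near-fixation = low values).
#' @param within_mode_fst differentiation among populations of the same mode
#'   (0: populations of a mode share their true frequencies).
#' @param snp_density expected SNPs per bp.
#' @param outgroup_divergence substitutions per site separating the outgroup
#'   from the ancestral sequence.
#' @param n_genes_candidate,n_genes_background protein-coding gene models
#'   placed inside the candidate interval / on the other chromosomes.
#' @param seed integer; fully determines all generator output.
#' @return a validated list of class `truth_config`.
#' @export
truth_config <- function(n_chromosomes = 4,
                         chrom_length = 2e6,
                         n_pops_per_mode = 3,
                         lineages_cp = c(21, 20, 20),
                         lineages_op = 14,
                         mean_depth_per_library = 17,
                         candidate_interval = list(chrom = "X",
                                                   start = 900000,
                                                   end = 1100000),
                         background_fst = 0.025,
                         candidate_fst = 0.35,
                         candidate_he_op = 0.14,
                         within_mode_fst = 0,
                         snp_density = 0.01,
                         outgroup_divergence = 0.01,
                         n_genes_candidate = 30,
                         n_genes_background = 8,
                         seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_pops_per_mode = as.integer(n_pops_per_mode),
    lineages_cp = rep_len(as.integer(lineages_cp), n_pops_per_mode),
    lineages_op = rep_len(as.integer(lineages_op), n_pops_per_mode),
    mean_depth_per_library = mean_depth_per_library,
    candidate_interval = candidate_interval,
    background_fst = background_fst,
    candidate_fst = candidate_fst,
    candidate_he_op = candidate_he_op,
    within_mode_fst = within_mode_fst,
    snp_density = snp_density,
    outgroup_divergence = outgroup_divergence,
    n_genes_candidate = as.integer(n_genes_candidate),
    n_genes_background = as.integer(n_genes_background),
    seed = as.integer(seed))
  fracs <- c(cfg$background_fst, cfg$candidate_fst, cfg$candidate_he_op,
             cfg$within_mode_fst, cfg$outgroup_divergence)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$candidate_he_op > 0.5) stop("candidate_he_op cannot exceed 0.5")
  ci <- cfg$candidate_interval
  chrom_names <- chromosome_names(cfg)
  if (!ci$chrom %in% chrom_names) {
    stop("candidate interval chromosome '", ci$chrom, "' not in genome")
  }
  if (ci$start < 0 || ci$end > cfg$chrom_length || ci$end <= ci$start) {
    stop("candidate interval outside its chromosome")
  }
  structure(cfg, class = "truth_config")
}

chromosome_names <- function(config) {
  n <- config$n_chromosomes
  if (n == 1L) return("X")
  c(paste0("chr", seq_len(n - 1)), "X")
}

#' Per-site Nei F_ST between two groups from true allele frequencies
#' @keywords internal
nei_fst_true <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  num <- (p1 - p2)^2 / 2
  ifelse(ht > 0, num / ht, NA_real_)
}

# Frequency pair with exact per-site Nei F_ST `fst`, OP near fixation with
# expected heterozygosity he_op. Returns c(p_cp, p_op) for the unflipped
# orientation (OP near 0).
candidate_freq_pair <- function(fst, he_op) {
  p_op <- (1 - sqrt(1 - 2 * he_op)) / 2
  if (fst <= 0) return(c(p_op, p_op))
  f <- function(p_cp) nei_fst_true(p_op, p_cp) - fst
  upper <- 1
  if (f(upper) < 0) stop("candidate_fst unreachable at this candidate_he_op")
  p_cp <- uniroot(f, c(min(p_op + 1e-9, 1), upper), tol = 1e-12)$root
  c(p_cp, p_op)
}

# Neutral-ish background frequency spectrum: ancestral-derived mean frequency
# drawn from a 1/i spectrum on a grid of m classes (m ~ pool size), then the
# two modes displaced symmetrically so the per-site Nei F_ST equals `fst`
# exactly where feasible.
background_freqs <- function(n_sites, fst, m = 30) {
  i <- seq_len(m - 1)
  pbar <- sample(i / m, n_sites, replace = TRUE, prob = 1 / i)
  delta <- sqrt(fst * pbar * (1 - pbar))
  delta <- pmin(delta, pbar, 1 - pbar)
  s <- sample(c(-1, 1), n_sites, replace = TRUE)
  cbind(cp = pbar + s * delta, op = pbar - s * delta)
}

#' Build a ground-truth allele-frequency landscape
#'
#' Draws, deterministically under `config$seed`: a random genome with
#' protein-coding gene models (stop-free CDS written into the reference), SNP
#' site positions, true derived-allele frequencies per population, and an
#' outgroup sequence diverged from the ancestral (reference) sequence.
#'
#' Background sites get a mean frequency from a truncated neutral (1/i)
#' spectrum with the two modes displaced so the per-site Nei F_ST equals
#' `background_fst`; candidate sites place OP near fixation (expected
#' heterozygosity `candidate_he_op`) and solve for the CP frequency giving a
#' per-site Nei F_ST of exactly `candidate_fst`, with a random allele flip per
#' site.
#'
#' @param config a [truth_config()].
#' @return an object of class `truth_state`: `$genome` (DNAStringSet),
#'   `$outgroup` (DNAStringSet), `$sites` (chrom, pos, ancestral, derived,
#'   is_candidate), `$freq` (sites x populations matrix of true derived-allele
#'   frequencies), `$genes` (`gene_models`), `$metadata` (library-level pool
#'   metadata), `$config`.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(config$seed)
  chroms <- chromosome_names(config)
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE),
          collapse = "")
  }, character(1)))
  names(genome) <- chroms

  genes <- simulate_gene_models(config)
  genome <- write_cds_into_genome(genome, genes)

  # SNP positions
  sites <- do.call(rbind, lapply(chroms, function(ch) {
    n <- rbinom(1, config$chrom_length, config$snp_density)
    pos <- sort(sample.int(config$chrom_length, n))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  ci <- config$candidate_interval
  sites$is_candidate <- sites$chrom == ci$chrom &
    (sites$pos - 1L) >= ci$start & (sites$pos - 1L) < ci$end

  anc <- unlist(lapply(chroms, function(ch) {
    p <- sites$pos[sites$chrom == ch]
    substring(as.character(genome[[ch]]), p, p)
  }), use.names = FALSE)
  derived <- other_base(anc)
  sites$ancestral <- anc
  sites$derived <- derived

  # true derived-allele frequency per mode
  n_sites <- nrow(sites)
  mode_freq <- matrix(0, n_sites, 2, dimnames = list(NULL, c("CP", "OP")))
  bg <- !sites$is_candidate
  mode_freq[bg, ] <- background_freqs(sum(bg), config$background_fst)
  if (any(sites$is_candidate)) {
    pair <- candidate_freq_pair(config$candidate_fst, config$candidate_he_op)
    flip <- sample(c(TRUE, FALSE), sum(sites$is_candidate), replace = TRUE)
    mode_freq[sites$is_candidate, "CP"] <- ifelse(flip, 1 - pair[1], pair[1])
    mode_freq[sites$is_candidate, "OP"] <- ifelse(flip, 1 - pair[2], pair[2])
  }

  # population frequencies; within_mode_fst = 0 duplicates the mode frequency
  pops <- c(paste0("CP", seq_len(config$n_pops_per_mode)),
            paste0("OP", seq_len(config$n_pops_per_mode)))
  modes <- rep(c("CP", "OP"), each = config$n_pops_per_mode)
  freq <- matrix(0, n_sites, length(pops), dimnames = list(NULL, pops))
  for (j in seq_along(pops)) {
    p <- mode_freq[, modes[j]]
    if (config$within_mode_fst > 0) {
      F <- config$within_mode_fst
      a <- p * (1 - F) / F
      b <- (1 - p) * (1 - F) / F
      ok <- p > 0 & p < 1
      p[ok] <- stats::rbeta(sum(ok), a[ok], b[ok])
    }
    freq[, j] <- p
  }

  outgroup <- mutate_outgroup(genome, config$outgroup_divergence)

  lineages <- c(config$lineages_cp, config$lineages_op)
  metadata <- data.frame(
    library_id = paste0(rep(pops, each = 2), c("a", "b")),
    population_id = rep(pops, each = 2),
    mode = rep(modes, each = 2),
    n_lineages = rep(lineages, each = 2),
    stringsAsFactors = FALSE)

  structure(list(genome = genome, outgroup = outgroup, sites = sites,
                 freq = freq, genes = genes, metadata = metadata,
                 config = config),
            class = "truth_state")
}

#' @export
print.truth_state <- function(x, ...) {
  cat(sprintf("truth_state: %d SNP sites (%d candidate) on %d chromosomes, %d genes\n",
              nrow(x$sites), sum(x$sites$is_candidate),
              length(x$genome), length(x$genes)))
  invisible(x)
}

# draw, for each input base, one of the three other bases uniformly
other_base <- function(base) {
  nt <- c("A", "C", "G", "T")
  i <- match(base, nt)
  j <- sample.int(3, length(base), replace = TRUE)
  nt[((i - 1L + j) %% 4L) + 1L]
}

mutate_outgroup <- function(genome, divergence) {
  out <- genome
  if (divergence <= 0) return(out)
  for (ch in names(genome)) {
    len <- length(genome[[ch]])
    n_sub <- rbinom(1, len, divergence)
    if (n_sub == 0) next
    pos <- sample.int(len, n_sub)
    old <- substring(as.character(genome[[ch]]), pos, pos)
    out[[ch]] <- Biostrings::replaceLetterAt(out[[ch]], pos, other_base(old))
  }
  out
}

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

simulate_gene_models <- function(config) {
  chroms <- chromosome_names(config)
  ci <- config$candidate_interval
  place_genes <- function(n, chrom, lo, hi, prefix) {
    if (n == 0) return(list())
    span <- hi - lo
    cursor <- lo + sample.int(200, 1)
    out <- list()
    for (k in seq_len(n)) {
      n_codons <- sample(150:450, 1)
      cds_len <- 3L * (n_codons + 1L)  # includes the stop codon
      n_exons <- sample(1:3, 1)
      cuts <- sort(sample.int(cds_len - 1, n_exons - 1))
      seg_len <- diff(c(0L, cuts, cds_len))
      introns <- if (n_exons > 1) sample(50:200, n_exons - 1, replace = TRUE) else integer(0)
      total <- cds_len + sum(introns)
      if (cursor + total >= hi) break
      starts <- cursor + c(0L, cumsum(seg_len[-n_exons] + introns))
      cds <- data.frame(start = starts, end = starts + seg_len)
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("%s%02d", prefix, k)
      out[[gid]] <- list(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                         chrom = chrom, strand = strand, cds = cds,
                         phase = 0L, usable = TRUE)
      cursor <- cursor + total + sample(500:2000, 1)
    }
    out
  }
  cand <- place_genes(config$n_genes_candidate, ci$chrom, ci$start, ci$end, "geneC")
  bg <- place_genes(config$n_genes_background, chroms[1],
                    1000L, config$chrom_length - 1000L, "geneB")
  structure(c(cand, bg), class = "gene_models")
}

# Overwrite gene loci with stop-free coding sequence (a random sense-codon
# message plus terminal stop), respecting strand and exon structure.
write_cds_into_genome <- function(genome, genes) {
  for (g in genes) {
    cds_len <- sum(g$cds$end - g$cds$start)
    n_codons <- cds_len %/% 3L - 1L
    coding <- paste0(paste(sample(SENSE_CODONS, n_codons, replace = TRUE),
                           collapse = ""), "TAA")
    s <- Biostrings::DNAString(coding)
    if (g$strand == "-") s <- Biostrings::reverseComplement(s)
    # lay genomic-order sequence across exons
    offset <- 0L
    for (i in seq_len(nrow(g$cds))) {
      seg <- g$cds$end[i] - g$cds$start[i]
      piece <- Biostrings::subseq(s, offset + 1L, offset + seg)
      genome[[g$chrom]] <- Biostrings::replaceAt(
        genome[[g$chrom]],
        IRanges::IRanges(g$cds$start[i] + 1L, g$cds$end[i]),
        piece)
      offset <- offset + seg
    }
  }
  genome
}

#' Sample Pool-seq libraries from a truth state
#'
#' Two-stage sampling: for every population the finite pool of
#' `2 * n_lineages` chromosomes is drawn binomially from the true population
#' frequency once (replicate libraries share the DNA pool), then each
#' library's reads are drawn binomially from the pool frequency at a depth
#' that is Poisson around `mean_depth_per_library`.
#'
#' @param truth a `truth_state`.
#' @param config the matching [truth_config()]; defaults to the one inside
#'   `truth`.
#' @return a library-level `pool_sync` over the truth's SNP sites; the pool
#'   metadata is in `truth$metadata`.
#' @export
sample_pools <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  md <- truth$metadata
  n_sites <- nrow(truth$sites)
  counts <- array(0L, dim = c(n_sites, 6, nrow(md)))
  anc_idx <- match(truth$sites$ancestral, SYNC_BASES)
  der_idx <- match(truth$sites$derived, SYNC_BASES)
  pops <- unique(md$population_id)
  for (pop in pops) {
    rows <- which(md$population_id == pop)
    n_chr <- 2L * md$n_lineages[rows[1]]
    p_true <- truth$freq[, pop]
    pool_freq <- rbinom(n_sites, n_chr, p_true) / n_chr
    for (j in rows) {
      depth <- rpois(n_sites, config$mean_depth_per_library)
      der <- rbinom(n_sites, depth, pool_freq)
      idx <- seq_len(n_sites)
      counts[cbind(idx, der_idx, j)] <- der
      counts[cbind(idx, anc_idx, j)] <-
        counts[cbind(idx, anc_idx, j)] + (depth - der)
    }
  }
  sync <- new_pool_sync(
    data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
               ref = truth$sites$ancestral, stringsAsFactors = FALSE),
    counts, md$library_id)
  sync
}

#' Simulate per-position sequencing depth tracks
#'
#' Independent Poisson depths for each library at every position of an
#' interval; used by the depth-ratio scan and for callable-site masks.
#'
#' @param n_positions number of positions.
#' @param mean_depth Poisson mean per library.
#' @param n_libraries number of tracks.
#' @param copy_number relative copy number per library (scales the mean).
#' @return an integer matrix `n_positions x n_libraries`.
#' @export
sample_depth_track <- function(n_positions, mean_depth, n_libraries = 1,
                               copy_number = 1) {
  copy_number <- rep_len(copy_number, n_libraries)
  vapply(seq_len(n_libraries), function(j) {
    rpois(n_positions, mean_depth * copy_number[j])
  }, integer(n_positions))
}

#' Write the outgroup FASTA of a truth state
#'
#' The outgroup sequence is the ancestral (reference) sequence with random
#' substitutions at rate `outgroup_divergence`, generated inside
#' [build_truth()] so that the seed determines it.
#'
#' @export
write_outgroup <- function(truth, path) {
  Biostrings::writeXStringSet(truth$outgroup, path)
  invisible(path)
}

#' Write a complete synthetic Pool-seq dataset to disk
#'
#' Emits the reference FASTA, outgroup FASTA, GFF3 gene models, library-level
#' sync file and pool metadata TSV for a truth state. With a fixed seed the
#' files are byte-identical across runs.
#'
#' @param truth a `truth_state`.
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_pool_dataset <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    outgroup = file.path(dir, "outgroup.fa"),
    genes = file.path(dir, "genes.gff3"),
    sync = file.path(dir, "pools.sync"),
    metadata = file.path(dir, "pools.tsv"))
  Biostrings::writeXStringSet(truth$genome, paths$reference)
  write_outgroup(truth, paths$outgroup)
  write_gene_models_gff3(truth$genes, paths$genes)
  write_sync(sample_pools(truth), paths$sync)
  write_pool_metadata(truth$metadata, paths$metadata)
  paths
}
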