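#' Pipeline run configuration
#'
#' Bundles a synthetic-data configuration (or paths to existing inputs) with
#' every analysis threshold; all thresholds default to the values used in the
#' analyses this package reimplements.
#'
#' @param truth a [truth_config()] when the run starts from simulation;
#'   NULL when `paths` point at existing inputs.
#' @param paths named list of existing inputs (`sync`, `metadata`,
#'   `reference`, `outgroup`, `genes`); filled in by the simulate stage when
#'   `truth` is given.
#' @param out_dir output directory.
#' @param mac_min,depth_min,depth_max,maf_min SNP calling/filtering thresholds.
#' @param fst_window,fst_step sliding-window geometry for the F_ST scan (bp).
#' @param stat_window contiguous window size for H_E / Tajima's D / FWH (bp).
#' @param fst_threshold window F_ST needed to seed a candidate region.
#' @param trim_fst per-SNP F_ST used to trim region boundaries.
#' @param assoc optional path to a per-SNP association score TSV
#'   (chrom, pos, score) computed externally; NULL disables confirmation.
#' @param assoc_threshold,min_assoc confirmation rule for regions.
#' @param depth_ratio_window depth-ratio window (bp).
#' @param target_coverage,max_coverage uniform subsampling bounds.
#' @param n_replicates consensus replicates for dating.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(truth = truth_config(), paths = list(),
                       out_dir = tempfile("poolscan_run_"),
                       mac_min = 4, depth_min = 20, depth_max = 60,
                       maf_min = 0.05,
                       fst_window = 20000, fst_step = 5000,
                       stat_window = 1e5,
                       fst_threshold = 0.25, trim_fst = 0.5,
                       assoc = NULL, assoc_threshold = 60, min_assoc = 1,
                       depth_ratio_window = 2000,
                       target_coverage = 30, max_coverage = 360,
                       n_replicates = 100, fwh = TRUE,
                       seed = if (!is.null(truth)) truth$seed else 1L) {
  structure(as.list(environment()), class = "run_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages run in dependency order — simulate (when configured), SNP calling
#' and filtering, window statistics, genome scan, divergence dating, variant
#' effect annotation — each writing plain files under `config$out_dir` so any
#' stage can be re-run in isolation from the files of the previous one. A JSON
#' manifest records the resolved configuration, seeds and output digests;
#' reruns with the same seed produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the manifest and the in-memory stage
#'   results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) {
    message(sprintf("[poolscan %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...)))
  }
  paths <- config$paths

  if (!is.null(config$truth)) {
    log_stage("simulate: seed %d", config$truth$seed)
    truth <- build_truth(config$truth)
    paths <- write_pool_dataset(truth, file.path(config$out_dir, "input"))
  }
  need <- c("sync", "metadata", "reference", "genes")
  if (!all(need %in% names(paths))) {
    stop("missing input(s): ", paste(setdiff(need, names(paths)), collapse = ", "))
  }
  if (isTRUE(config$fwh) && is.null(paths$outgroup)) {
    stop("Fay & Wu's H requested but no outgroup FASTA configured")
  }

  log_stage("filter: reading sync + calling SNPs")
  metadata <- read_pool_metadata(paths$metadata)
  sync <- read_sync(paths$sync, metadata)
  by_pop <- merge_replicate_libraries(sync, metadata)
  snps_all <- call_snps(by_pop, config$mac_min)
  snps <- filter_snps(snps_all, config$depth_min, config$depth_max,
                      config$maf_min)
  genome <- Biostrings::readDNAStringSet(paths$reference)
  names(genome) <- sub("\\s.*", "", names(genome))
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  snp_tsv <- data.frame(snps$info, depth = snp_depth(snps))
  write_tsv(data.frame(snps_all$info), file.path(config$out_dir, "snps_nonfiltered.tsv"))
  write_tsv(snp_tsv, file.path(config$out_dir, "snps_filtered.tsv"))
  log_stage("filter: %d called, %d after depth/MAF filters",
            nrow(snps_all$info), nrow(snps$info))

  log_stage("stats: F_ST / H_E / D / FWH windows")
  fst <- fst_by_mode(snps)
  fst_win <- fst_windows(fst$snp, chrom_lengths, config$fst_window,
                         config$fst_step)
  he_win <- he_windows(snps, chrom_lengths, config$stat_window)
  outgroup <- NULL
  if (!is.null(paths$outgroup)) {
    outgroup <- Biostrings::readDNAStringSet(paths$outgroup)
    names(outgroup) <- sub("\\s.*", "", names(outgroup))
  }
  set.seed(config$seed + 101L)
  sfs_cp <- sfs_window_stats(snps_all, "CP", outgroup, chrom_lengths,
                             config$stat_window, config$target_coverage,
                             config$max_coverage)
  set.seed(config$seed + 102L)
  sfs_op <- sfs_window_stats(snps_all, "OP", outgroup, chrom_lengths,
                             config$stat_window, config$target_coverage,
                             config$max_coverage)
  write_tsv(data.frame(fst$snp[, c("chrom", "pos", "fst")]),
            file.path(config$out_dir, "fst_per_snp.tsv"))
  write_tsv(fst_win, file.path(config$out_dir, "fst_windows.tsv"))
  write_tsv(he_win, file.path(config$out_dir, "he_windows.tsv"))
  write_tsv(sfs_cp, file.path(config$out_dir, "sfs_windows_cp.tsv"))
  write_tsv(sfs_op, file.path(config$out_dir, "sfs_windows_op.tsv"))
  log_stage("stats: multilocus between-mode F_ST = %.4f", fst$multilocus)

  log_stage("scan: delimiting candidate regions")
  assoc <- if (!is.null(config$assoc)) {
    read.table(config$assoc, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  } else NULL
  regions <- delimit_candidate_region(fst_win, fst$snp, assoc,
                                      config$fst_threshold,
                                      config$assoc_threshold,
                                      config$min_assoc, config$trim_fst)
  if (nrow(regions) > 0) {
    bed <- regions[order(-regions$mean_fst), ]
    writeLines(sprintf("%s\t%d\t%d\tcandidate_%d\t%.4f", bed$chrom, bed$start,
                       bed$end, seq_len(nrow(bed)), bed$mean_fst),
               file.path(config$out_dir, "candidate_regions.bed"))
  } else {
    writeLines(character(0), file.path(config$out_dir, "candidate_regions.bed"))
  }
  log_stage("scan: %d region(s)", nrow(regions))

  dating <- NULL
  effects_tbl <- gene_summary <- NULL
  comparisons <- NULL
  if (nrow(regions) > 0) {
    main <- regions[which.max(regions$mean_fst), ]
    region <- list(chrom = main$chrom, start = main$start, end = main$end)

    comparisons <- list(
      he_op = compare_candidate_vs_rest(he_win, main, "he_op"),
      tajimas_d_op = compare_candidate_vs_rest(sfs_op, main, "tajimas_d"),
      he_modes = compare_modes_paired(he_win$he_cp, he_win$he_op))

    log_stage("date: %s:%d-%d, %d consensus replicates", region$chrom,
              region$start, region$end, config$n_replicates)
    rates <- compose_mutation_rates()
    dating <- date_region(snps_all, region, genome,
                          read_gff_cds(paths$genes), rates,
                          n_sites = NULL,
                          n_replicates = config$n_replicates,
                          seed = config$seed + 103L)
    dating_json <- lapply(
      dating[c("da", "substitution_count", "ds_calibrated")],
      function(e) {
        if (is.null(e)) return(NULL)
        list(method = e$method, t_years = e$t_years, ci95 = unname(e$ci95),
             inputs = e$inputs)
      })
    jsonlite::write_json(dating_json,
                         file.path(config$out_dir, "divergence_estimates.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")

    log_stage("annotate: classifying high-F_ST variants")
    genes <- read_gff_cds(paths$genes)
    variants <- data.frame(snps$info[, c("chrom", "pos")],
                           ref = snps$info$major, alt = snps$info$minor,
                           fst = fst$snp$fst,
                           stringsAsFactors = FALSE)
    depth <- snp_depth(snps)
    colnames(depth) <- paste0("depth_", snps$populations$population_id)
    variants <- cbind(variants, depth)
    in_region <- variants$chrom == region$chrom &
      (variants$pos - 1L) >= region$start & (variants$pos - 1L) < region$end
    cand <- select_candidate_variants(variants[in_region, , drop = FALSE],
                                      fst_min = config$trim_fst,
                                      depth_min = config$depth_min)
    # effect classification uses the ancestral reference orientation
    ref_base <- mapply(function(ch, p) {
      as.character(Biostrings::subseq(genome[[ch]], p, p))
    }, cand$chrom, cand$pos, USE.NAMES = FALSE)
    flip <- cand$ref != ref_base
    tmp <- cand$ref[flip]
    cand$ref[flip] <- cand$alt[flip]
    cand$alt[flip] <- tmp
    effects_tbl <- classify_variants(cand, genes, genome)
    gene_summary <- per_gene_summary(effects_tbl, genes)
    write_tsv(effects_tbl, file.path(config$out_dir, "variant_effects.tsv"))
    write_tsv(gene_summary, file.path(config$out_dir, "gene_summary.tsv"))
  }

  outputs <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("poolscan")),
    seed = config$seed,
    thresholds = config[c("mac_min", "depth_min", "depth_max", "maf_min",
                          "fst_window", "fst_step", "stat_window",
                          "fst_threshold", "trim_fst", "assoc_threshold",
                          "min_assoc", "depth_ratio_window",
                          "target_coverage", "max_coverage", "n_replicates")],
    inputs = paths,
    output_md5 = as.list(tools::md5sum(outputs)),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done in %.1f s", manifest$elapsed_s)
  invisible(list(manifest = manifest, snps = snps, fst = fst,
                 fst_windows = fst_win, he_windows = he_win,
                 sfs_cp = sfs_cp, sfs_op = sfs_op,
                 regions = regions, comparisons = comparisons,
                 dating = dating, effects = effects_tbl,
                 gene_summary = gene_summary, paths = paths))
}
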