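#' @importFrom stats rbinom rpois runif quantile median wilcox.test rhyper uniroot setNames
#' @importFrom utils read.table write.table
NULL

SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' Read pool metadata
#'
#' Reads the tab-separated pool description used throughout the pipeline:
#' one row per sequencing library with columns `library_id`, `population_id`,
#' `mode` (`CP` or `OP`) and `n_lineages` (clonal lineages contributing to the
#' pool; pool size in chromosomes is `2 * n_lineages`).
#'
#' @param path path to a tab-separated file with a header line.
#' @return a `data.frame` with the four columns above.
#' @export
read_pool_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_pool_metadata(md)
  md
}

validate_pool_metadata <- function(metadata) {
  need <- c("library_id", "population_id", "mode", "n_lineages")
  missing <- setdiff(need, names(metadata))
  if (length(missing) > 0) {
    stop("pool metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(metadata$library_id)) {
    stop("duplicated library_id in pool metadata")
  }
  if (!all(metadata$mode %in% c("CP", "OP"))) {
    stop("mode must be 'CP' or 'OP'")
  }
  if (any(metadata$n_lineages < 1)) stop("n_lineages must be >= 1")
  invisible(metadata)
}

#' @export
write_pool_metadata <- function(metadata, path) {
  validate_pool_metadata(metadata)
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_pool_sync <- function(sites, counts, libraries) {
  stopifnot(is.data.frame(sites), length(dim(counts)) == 3)
  stopifnot(nrow(sites) == dim(counts)[1], dim(counts)[2] == 6)
  dimnames(counts) <- list(NULL, SYNC_BASES, libraries)
  structure(list(sites = sites, counts = counts, libraries = libraries),
            class = "pool_sync")
}

#' @export
print.pool_sync <- function(x, ...) {
  cat(sprintf("pool_sync: %d positions x %d libraries (%s)\n",
              nrow(x$sites), length(x$libraries),
              paste(utils::head(x$libraries, 6), collapse = ", ")))
  invisible(x)
}

#' Read a sync file of pooled allele counts
#'
#' The sync format is tab-separated: chromosome, 1-based position, reference
#' base, then one `A:T:C:G:N:del` colon-separated count field per library.
#' The parse is lossless: N and deletion counts are retained (they are
#' excluded later, at SNP-calling time, from depth and allele counts).
#'
#' @param path sync file path.
#' @param metadata pool metadata (`read_pool_metadata()`); its rows must match
#'   the count columns of the file, in order.
#' @return a `pool_sync` object: `$sites` (chrom, pos, ref), `$counts`
#'   (positions x 6 bases x libraries integer array), `$libraries`.
#' @export
read_sync <- function(path, metadata) {
  validate_pool_metadata(metadata)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_lib <- nrow(metadata)
  if (length(lines) == 0) {
    return(new_pool_sync(
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 stringsAsFactors = FALSE),
      array(0L, dim = c(0, 6, n_lib)), metadata$library_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3 + n_lib)) {
    bad <- which(nf != 3 + n_lib)[1]
    stop(sprintf("sync line %d has %d columns; expected %d (3 + %d libraries)",
                 bad, nf[bad], 3 + n_lib, n_lib))
  }
  m <- matrix(unlist(fields), ncol = 3 + n_lib, byrow = TRUE)
  sites <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), ref = m[, 3],
                      stringsAsFactors = FALSE)
  if (any(is.na(sites$pos)) || any(sites$pos < 1)) {
    stop("sync positions must be integers >= 1")
  }
  counts <- array(0L, dim = c(nrow(sites), 6, n_lib))
  for (j in seq_len(n_lib)) {
    parts <- strsplit(m[, 3 + j], ":", fixed = TRUE)
    if (any(lengths(parts) != 6)) {
      bad <- which(lengths(parts) != 6)[1]
      stop(sprintf("sync line %d: count field '%s' does not have 6 values",
                   bad, m[bad, 3 + j]))
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v) || any(v < 0)) {
      bad <- which(is.na(v) | v < 0)[1]
      stop(sprintf("sync line %d: malformed count field '%s'",
                   (bad - 1) %/% 6 + 1, m[(bad - 1) %/% 6 + 1, 3 + j]))
    }
    counts[, , j] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  new_pool_sync(sites, counts, metadata$library_id)
}

#' Write a `pool_sync` object to a sync file
#' @export
write_sync <- function(sync, path) {
  n_lib <- length(sync$libraries)
  cols <- vapply(seq_len(n_lib), function(j) {
    apply(sync$counts[, , j, drop = FALSE], 1, paste, collapse = ":")
  }, character(nrow(sync$sites)))
  if (nrow(sync$sites) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  cols <- matrix(cols, nrow = nrow(sync$sites))
  lines <- paste(sync$sites$chrom, sync$sites$pos, sync$sites$ref,
                 apply(cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

sum_library_groups <- function(sync, groups) {
  ids <- unique(groups$group)
  out <- array(0L, dim = c(nrow(sync$sites), 6, length(ids)))
  for (g in seq_along(ids)) {
    libs <- groups$library_id[groups$group == ids[g]]
    j <- match(libs, sync$libraries)
    if (anyNA(j)) stop("metadata names libraries absent from the sync object")
    sub <- sync$counts[, , j, drop = FALSE]
    out[, , g] <- rowSums(sub, dims = 2)
  }
  new_pool_sync(sync$sites, out, ids)
}

#' Sum replicate libraries into one count vector per population
#'
#' Replicate sequencing libraries of the same DNA pool carry no additional
#' biological information, so their allele counts are summed position-wise,
#' as if each population had been sequenced in a single library. Total depth
#' is conserved.
#'
#' @param sync a `pool_sync` whose columns are libraries.
#' @param metadata pool metadata mapping libraries to populations.
#' @return a `pool_sync` whose columns are populations, with an attached
#'   population-level metadata attribute (`population_id`, `mode`,
#'   `n_lineages`).
#' @export
merge_replicate_libraries <- function(sync, metadata) {
  validate_pool_metadata(metadata)
  merged <- sum_library_groups(
    sync, data.frame(library_id = metadata$library_id,
                     group = metadata$population_id,
                     stringsAsFactors = FALSE))
  pop_md <- unique(metadata[, c("population_id", "mode", "n_lineages")])
  if (anyDuplicated(pop_md$population_id)) {
    stop("inconsistent mode/n_lineages across replicate libraries")
  }
  pop_md <- pop_md[match(merged$libraries, pop_md$population_id), ]
  attr(merged, "populations") <- pop_md
  merged
}

#' Sum population counts by reproductive mode
#'
#' Groups the populations of each reproductive mode (CP, OP) into a single
#' pooled count vector per position, which gives more precise mode-level
#' allele-frequency estimates than any single population.
#'
#' @param sync a population-level `pool_sync` (from
#'   [merge_replicate_libraries()]).
#' @param metadata pool metadata (library- or population-level).
#' @return a `pool_sync` with two columns, `CP` and `OP`; attribute
#'   `pool_size` gives the number of chromosomes per mode
#'   (`2 * sum(n_lineages)`).
#' @export
pool_by_mode <- function(sync, metadata) {
  pops <- attr(sync, "populations")
  if (is.null(pops)) {
    validate_pool_metadata(metadata)
    pops <- unique(metadata[, c("population_id", "mode", "n_lineages")])
  }
  pops <- pops[match(sync$libraries, pops$population_id), ]
  if (anyNA(pops$mode)) stop("sync columns missing from metadata")
  pooled <- sum_library_groups(
    sync, data.frame(library_id = pops$population_id, group = pops$mode,
                     stringsAsFactors = FALSE))
  sizes <- tapply(pops$n_lineages, pops$mode, function(x) 2L * sum(x))
  attr(pooled, "pool_size") <- sizes[pooled$libraries]
  pooled
}

#' Restrict a `pool_sync` to a genomic interval
#'
#' @param sync a `pool_sync`.
#' @param chrom chromosome id.
#' @param start,end 0-based half-open interval bounds.
#' @export
restrict_sync <- function(sync, chrom, start, end) {
  keep <- sync$sites$chrom == chrom &
    (sync$sites$pos - 1L) >= start & (sync$sites$pos - 1L) < end
  out <- new_pool_sync(sync$sites[keep, , drop = FALSE],
                       sync$counts[keep, , , drop = FALSE], sync$libraries)
  attr(out, "populations") <- attr(sync, "populations")
  attr(out, "pool_size") <- attr(sync, "pool_size")
  out
}
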