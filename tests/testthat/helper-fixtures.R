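# Shared fixtures for the test suite; everything is generated in code.

.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

two_library_metadata <- function() {
  data.frame(library_id = c("P1a", "P1b"),
             population_id = c("P1", "P1"),
             mode = c("CP", "CP"),
             n_lineages = c(20L, 20L),
             stringsAsFactors = FALSE)
}

six_pop_metadata <- function() {
  data.frame(library_id = paste0(rep(c("CP1", "CP2", "CP3", "OP1", "OP2", "OP3"),
                                     each = 2), c("a", "b")),
             population_id = rep(c("CP1", "CP2", "CP3", "OP1", "OP2", "OP3"),
                                 each = 2),
             mode = rep(c("CP", "OP"), each = 6),
             n_lineages = rep(c(21L, 20L, 20L, 14L, 14L, 14L), each = 2),
             stringsAsFactors = FALSE)
}

write_sync_lines <- function(lines) {
  path <- tempfile(fileext = ".sync")
  writeLines(lines, path)
  path
}

# population-level pool_sync built directly from a list of per-position,
# per-population six-vectors (A,T,C,G,N,del)
make_pop_sync <- function(counts_by_pop, pops, chrom = "X",
                          pos = seq_along(counts_by_pop),
                          ref = rep("A", length(counts_by_pop))) {
  n_pop <- nrow(pops)
  arr <- array(0L, dim = c(length(counts_by_pop), 6, n_pop))
  for (i in seq_along(counts_by_pop)) {
    arr[i, , ] <- matrix(as.integer(unlist(counts_by_pop[[i]])), nrow = 6)
  }
  sync <- poolscan:::new_pool_sync(
    data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
               stringsAsFactors = FALSE),
    arr, pops$population_id)
  attr(sync, "populations") <- pops
  sync
}

six_pops <- function() {
  data.frame(population_id = c("CP1", "CP2", "CP3", "OP1", "OP2", "OP3"),
             mode = rep(c("CP", "OP"), each = 3),
             n_lineages = c(21L, 20L, 20L, 14L, 14L, 14L),
             stringsAsFactors = FALSE)
}

# a biallelic A/C six-vector with given counts
ac_counts <- function(a, c) c(a, 0L, c, 0L, 0L, 0L)

small_truth_config <- function(seed = 1, ...) {
  truth_config(n_chromosomes = 2, chrom_length = 4e5,
               candidate_interval = list(chrom = "X", start = 120000,
                                         end = 280000),
               snp_density = 0.003, n_genes_candidate = 8,
               n_genes_background = 2, seed = seed, ...)
}

small_truth <- function(seed = 1) {
  cache_fixture(paste0("truth_", seed),
                function() build_truth(small_truth_config(seed)))
}

# toy genome/gene fixture for variant-effect tests:
# chrom "c1": single-exon plus-strand gene, CDS "ATG AAA TAG" at 1-based 3..11
# chrom "c2": its reverse complement as a minus-strand gene, plus a
#             two-exon minus-strand gene for splice/intron cases
effects_fixture <- function() {
  cache_fixture("effects_fixture", function() {
    genome <- Biostrings::DNAStringSet(c(
      c1 = "GGATGAAATAGGGGGGGGGG",
      #     123456789012345678901234567890123456789
      c2 = "GGCTATTTCATGGGGGATGGCATTTGGCCCAAGTAGGCCC"))
    genes <- structure(list(
      fwd = list(gene_id = "fwd", transcript_id = "fwd.t1", chrom = "c1",
                 strand = "+",
                 cds = data.frame(start = 2L, end = 11L),
                 phase = 0L, usable = TRUE),
      rev = list(gene_id = "rev", transcript_id = "rev.t1", chrom = "c2",
                 strand = "-",
                 cds = data.frame(start = 2L, end = 11L),
                 phase = 0L, usable = TRUE),
      # two-exon minus-strand gene; spliced CDS (translation order) is
      # rc("ATGGCATTT" + "TAGGCC") = "GGCCTAAAATGCCAT", stop-free
      twoex = list(gene_id = "twoex", transcript_id = "twoex.t1", chrom = "c2",
                   strand = "-",
                   cds = data.frame(start = c(16L, 33L), end = c(25L, 39L)),
                   phase = 0L, usable = TRUE)),
      class = "gene_models")
    list(genome = genome, genes = genes)
  })
}
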