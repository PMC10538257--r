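#!/usr/bin/env Rscript
# Stage 3: window statistics per reproductive mode.
#
# Between-mode F_ST per SNP (pool- and depth-corrected estimator) and in
# 20-kb windows sliding by 5 kb; expected heterozygosity, pooled Tajima's D
# (uniform 30x subsample) and outgroup-polarized Fay & Wu's H in 100-kb
# contiguous windows.

suppressMessages(library(poolscan))

metadata <- read_pool_metadata("results/data/pools.tsv")
sync <- read_sync("results/data/pools.sync", metadata)
by_pop <- merge_replicate_libraries(sync, metadata)
snps_all <- call_snps(by_pop)
snps <- filter_snps(snps_all)

genome <- Biostrings::readDNAStringSet("results/data/reference.fa")
names(genome) <- sub("\\s.*", "", names(genome))
outgroup <- Biostrings::readDNAStringSet("results/data/outgroup.fa")
names(outgroup) <- sub("\\s.*", "", names(outgroup))
lens <- setNames(Biostrings::width(genome), names(genome))

fst <- fst_by_mode(snps)
message(sprintf("genome-wide between-mode F_ST (multilocus): %.4f",
                fst$multilocus))

fst_win <- fst_windows(fst$snp, lens, size = 20000, step = 5000)
he_win <- he_windows(snps, lens, size = 1e5)
set.seed(431)
sfs_cp <- sfs_window_stats(snps_all, "CP", outgroup, lens, size = 1e5)
set.seed(432)
sfs_op <- sfs_window_stats(snps_all, "OP", outgroup, lens, size = 1e5)

write.table(fst$snp[, c("chrom", "pos", "fst")], "results/fst_per_snp.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(fst_win, "results/fst_windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(he_win, "results/he_windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sfs_cp, "results/sfs_windows_cp.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sfs_op, "results/sfs_windows_op.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("median H_E: CP %.3f, OP %.3f (paired Wilcoxon p = %.2g)",
                median(he_win$he_cp, na.rm = TRUE),
                median(he_win$he_op, na.rm = TRUE),
                compare_modes_paired(he_win$he_cp, he_win$he_op)$p_value))
message(sprintf("median Tajima's D: CP %.3f, OP %.3f",
                median(sfs_cp$tajimas_d, na.rm = TRUE),
                median(sfs_op$tajimas_d, na.rm = TRUE)))
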