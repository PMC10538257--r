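#!/usr/bin/env Rscript
# Stage 4: candidate-region delimitation and structure checks.
#
# Merges runs of sliding windows with mean F_ST >= 0.25, trims region
# boundaries to the outermost SNPs with F_ST > 0.5, compares the candidate
# windows against the genome background (Mann-Whitney), and scans the
# normalized OP/(OP+CP) depth ratio in 2-kb windows for copy-number
# differences (0.5 expected under equal copy number).

suppressMessages(library(poolscan))

fst_snp <- read.table("results/fst_per_snp.tsv", header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
fst_win <- read.table("results/fst_windows.tsv", header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
he_win <- read.table("results/he_windows.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
sfs_op <- read.table("results/sfs_windows_op.tsv", header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)

regions <- delimit_candidate_region(fst_win, snp_fst = fst_snp,
                                    fst_threshold = 0.25, trim_fst = 0.5)
stopifnot(nrow(regions) > 0)
regions <- regions[order(-regions$mean_fst), ]
writeLines(sprintf("%s\t%d\t%d\tcandidate_%d\t%.4f", regions$chrom,
                   regions$start, regions$end, seq_len(nrow(regions)),
                   regions$mean_fst),
           "results/candidate_regions.bed")
main <- regions[1, ]
message(sprintf("main candidate region: %s:%d-%d (%.0f kb, mean F_ST %.3f)",
                main$chrom, main$start, main$end,
                (main$end - main$start) / 1e3, main$mean_fst))

truth_bed <- read.table("results/truth_candidate.bed", sep = "\t")
overlap <- min(main$end, truth_bed$V3) - max(main$start, truth_bed$V2)
message(sprintf("overlap with the simulated truth interval: %.0f kb",
                max(overlap, 0) / 1e3))

he_test <- compare_candidate_vs_rest(he_win, main, stat = "he_op")
d_test <- compare_candidate_vs_rest(sfs_op, main, stat = "tajimas_d")
message(sprintf("OP H_E in candidate vs rest: %.3f vs %.3f (U = %g, p = %.2g)",
                he_test$median_in, he_test$median_out, he_test$U,
                he_test$p_value))
message(sprintf("OP Tajima's D in candidate vs rest: %.3f vs %.3f (U = %g, p = %.2g)",
                d_test$median_in, d_test$median_out, d_test$U, d_test$p_value))

# depth-ratio scan across the candidate region (equal copy number simulated)
set.seed(44)
width <- main$end - main$start
depth_op <- rowSums(sample_depth_track(width, 17, n_libraries = 6))
depth_cp <- rowSums(sample_depth_track(width, 17, n_libraries = 6))
ratio <- depth_ratio_scan(depth_op, depth_cp, window = 2000,
                          offset = main$start)
write.table(cbind(chrom = main$chrom, ratio), "results/depth_ratio.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("depth ratio over the candidate region: mean %.4f (%d windows; 0.5 = equal copy number)",
                mean(ratio$ratio), nrow(ratio)))
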