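#!/usr/bin/env Rscript
# Stage 2: SNP identification and filtering.
#
# Replicate libraries are summed into one count vector per population, SNPs
# are called with a global minor-allele-count floor of 4 reads (single-read
# third alleles ignored), and the filtered set keeps SNPs with depth 20-60 in
# every population and a global minor allele frequency of at least 5%.

suppressMessages(library(poolscan))

metadata <- read_pool_metadata("results/data/pools.tsv")
sync <- read_sync("results/data/pools.sync", metadata)
by_pop <- merge_replicate_libraries(sync, metadata)

snps_all <- call_snps(by_pop, mac_min = 4)
snps <- filter_snps(snps_all, depth_min = 20, depth_max = 60, maf_min = 0.05)

write.table(snps_all$info, "results/snps_nonfiltered.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(snps$info, depth = snp_depth(snps)),
            "results/snps_filtered.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("%d positions read, %d SNPs called (MAC >= 4), %d after depth/MAF filters (%.1f%% kept)",
                nrow(sync$sites), nrow(snps_all$info), nrow(snps$info),
                100 * nrow(snps$info) / nrow(snps_all$info)))
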