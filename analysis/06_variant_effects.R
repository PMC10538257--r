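#!/usr/bin/env Rscript
# Stage 6: coding impact of the highly differentiated variants.
#
# Variants of the candidate region with F_ST > 0.5 and depth >= 20 in every
# population are classified against the gene models (missense, nonsense,
# frameshift, in-frame indel, synonymous, intronic...) and summarized per
# gene.

suppressMessages(library(poolscan))

metadata <- read_pool_metadata("results/data/pools.tsv")
sync <- read_sync("results/data/pools.sync", metadata)
snps <- filter_snps(call_snps(merge_replicate_libraries(sync, metadata)))
fst <- fst_by_mode(snps)
genome <- Biostrings::readDNAStringSet("results/data/reference.fa")
names(genome) <- sub("\\s.*", "", names(genome))
genes <- read_gff_cds("results/data/genes.gff3")

bed <- read.table("results/candidate_regions.bed", sep = "\t",
                  stringsAsFactors = FALSE)
region <- list(chrom = bed$V1[1], start = bed$V2[1], end = bed$V3[1])

depth <- snp_depth(snps)
colnames(depth) <- paste0("depth_", snps$populations$population_id)
variants <- cbind(data.frame(chrom = snps$info$chrom, pos = snps$info$pos,
                             ref = snps$info$major, alt = snps$info$minor,
                             fst = fst$snp$fst, stringsAsFactors = FALSE),
                  depth)
in_region <- variants$chrom == region$chrom &
  (variants$pos - 1) >= region$start & (variants$pos - 1) < region$end
cand <- select_candidate_variants(variants[in_region, ], fst_min = 0.5,
                                  depth_min = 20)
message(sprintf("%d candidate-region variants with F_ST > 0.5 and depth >= 20 everywhere",
                nrow(cand)))

# orient alleles to the reference base before translating
ref_base <- mapply(function(ch, p) {
  as.character(Biostrings::subseq(genome[[ch]], p, p))
}, cand$chrom, cand$pos, USE.NAMES = FALSE)
flip <- cand$ref != ref_base
tmp <- cand$ref[flip]
cand$ref[flip] <- cand$alt[flip]
cand$alt[flip] <- tmp

effects <- classify_variants(cand, genes, genome)
summary <- per_gene_summary(effects, genes)
write.table(effects, "results/variant_effects.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(summary, "results/gene_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

counts <- table(factor(effects$impact, c("high", "moderate", "low", "modifier")))
message(sprintf("impact classes: high %d, moderate %d, low %d, modifier %d",
                counts["high"], counts["moderate"], counts["low"],
                counts["modifier"]))
affected <- summary[summary$nonsense + summary$frameshift + summary$missense +
                      summary$inframe > 0, ]
message(sprintf("%d of %d genes carry protein-changing candidate variants",
                nrow(affected), nrow(summary)))
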