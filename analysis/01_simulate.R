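#!/usr/bin/env Rscript
# Stage 1: generate the synthetic Pool-seq study.
#
# Draws the ground-truth allele-frequency landscape (six populations, three
# per reproductive mode, two replicate libraries each) with one strongly
# differentiated 200-kb candidate interval on the X chromosome, and writes
# the sync file, reference and outgroup FASTA, GFF3 gene models and pool
# metadata under results/data/.

suppressMessages(library(poolscan))

cfg <- truth_config(seed = 42)
truth <- build_truth(cfg)
paths <- write_pool_dataset(truth, "results/data")

ci <- cfg$candidate_interval
message(sprintf("genome: %d chromosomes x %.1f Mb, %d SNP sites (%d in the candidate interval %s:%d-%d)",
                cfg$n_chromosomes, cfg$chrom_length / 1e6, nrow(truth$sites),
                sum(truth$sites$is_candidate), ci$chrom, ci$start, ci$end))
message(sprintf("gene models: %d (%d inside the candidate interval)",
                length(truth$genes), cfg$n_genes_candidate))
message("wrote: ", paste(unlist(paths), collapse = ", "))

# the truth interval is recorded so later stages can score localization
writeLines(sprintf("%s\t%d\t%d\ttruth_candidate", ci$chrom, ci$start, ci$end),
           "results/truth_candidate.bed")
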