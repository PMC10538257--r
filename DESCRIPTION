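Package: poolscan
Title: Pool-Seq Genome Scans and Allele Divergence Dating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing and dating a locus under divergent selection
    from pooled whole-genome sequencing (Pool-seq) of populations that differ
    in a binary phenotype. Implements pooled SNP calling and filtering from
    sync-format allele counts, per-SNP and windowed F_ST (Nei and a pool- and
    depth-corrected identity-probability estimator), expected heterozygosity,
    pooled Tajima's D and Fay and Wu's H via depth subsampling and outgroup
    polarization, candidate-region delimitation, a sequencing-depth-ratio scan
    for copy-number differences, coding variant-effect classification against
    GFF3 gene models, and three divergence-time estimators for the alleles of
    the candidate region (net divergence, consensus substitution counts, and
    dS calibration with NG86 synonymous distances). A synthetic-data generator
    produces ground-truth allele-frequency landscapes, sync files, reference
    and outgroup FASTA and GFF3 gene models so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
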