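---
title: "Pool-seq genome scans and allele divergence dating with poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq genome scans and allele divergence dating with poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Some pea aphid (*Acyrthosiphon pisum*) lineages reproduce by cyclical
parthenogenesis (CP: many clonal generations plus one sexual generation per
year, producing frost-resistant eggs), while others are obligate parthenogens
(OP) that have lost the sexual phase but may still produce functional males.
The two reproductive modes segregate in the wild as an X-linked allelic
polymorphism (the recessive *op* allele against *cp*). Because obligate
asexuality cannot be crossed into a mapping panel at scale, the locus is
localized by a population genomic contrast: pools of clonal lineages from
populations of each mode are sequenced (Pool-seq), and the genome is scanned
for regions where allele frequencies differ far more between modes than the
genome-wide background. The same pooled frequencies then support diversity
statistics inside the region (is the *op* haplotype a derived, swept allele?),
a depth-ratio scan for structural differences, the coding impact of the
differentiated variants, and three estimators of how long ago the *op* and
*cp* allelic classes diverged.

`poolscan` implements that whole chain as reusable functions plus an
orchestrated pipeline (`run_all()`), and ships a synthetic-data generator so
every stage is testable without any sequencing data. The numbered scripts
under `analysis/` run the pipeline end to end on a simulated study and narrate
what each stage finds.

## Input model

The pipeline consumes pooled allele counts in sync format (tab-separated:
chromosome, 1-based position, reference base, then one `A:T:C:G:N:del` count
field per library), pool metadata (library, population, mode, number of
lineages), a reference FASTA, an outgroup FASTA in reference coordinates, and
GFF3 gene models. Internally all coordinates are 0-based half-open; file I/O
respects each format's native convention. The N and deletion columns are
parsed and carried, but depth is defined as `A+T+C+G`: quality-filtered
substitutions are what the estimators consume, and indel discovery from sync
counts is out of scope (indels enter effect classification as explicit
ref/alt records).

Replicate libraries of one population are summed into a single count vector
(`merge_replicate_libraries()`); the populations of each mode are summed again
(`pool_by_mode()`) when a mode-level frequency is wanted, which sharpens the
frequency estimate at the cost of pooling demes. Pool sizes are tracked in
chromosomes (`2 * n_lineages`, the pools being diploid females).

## SNP calling and filtering

A position is a SNP when at least two nucleotides are observed and the global
minor allele count (summed over all populations) reaches `mac_min = 4` reads.
Triallelic positions whose third allele carries exactly one read are treated
as sequencing noise: the read is ignored and the site kept biallelic; a third
allele with two or more reads discards the site. The analysis set then keeps
SNPs whose per-population depth lies in `[20, 60]` — low depth gives unusable
frequency estimates, high depth flags collapsed duplications — and whose
global minor allele frequency is at least 5%. Both depth bounds and the MAF
floor are inclusive; the joint (all-population) reading of the MAC rule and
the global reading of the MAF rule are design choices, recorded here because
reasonable per-population variants exist.

## Differentiation and diversity statistics

**F_ST.** Two per-SNP estimators are provided. `nei` is the plug-in
`(H_T - H_S)/H_T` with `H_S` the mean within-mode heterozygosity and `H_T`
the heterozygosity at the mean frequency. The default `pool_corrected`
estimator de-biases the within-mode heterozygosities for the two-stage
sampling of Pool-seq — an observed `2p(1-p)` at read depth `d` from a pool
of `n` chromosomes is inflated by `d/(d-1) * n/(n-1)`, which removes the
`1/d` and `1/n` identity-by-sampling terms — and recombines the total on the
Nei scale as `H_T = (H_S + pi_between)/2`, where
`pi_between = p1(1-p2) + p2(1-p1)` is unbiased across independent pools. It
converges to the Nei estimator as depth and pool size grow and may be
slightly negative at undifferentiated SNPs, the usual price of unbiasedness.
Multilocus and windowed values are always ratios of summed numerators to
summed denominators, never means of per-SNP ratios. The sliding F_ST scan
uses 20-kb windows stepped by 5 kb; contiguous 100-kb windows serve the
diversity statistics.

Absolute genome-wide F_ST values depend on the data and the estimator behind
the original analyses (a pool-aware package whose exact formula is not
printed); they are therefore validated here as recovery of simulated truth,
not as fixed constants.

**Expected heterozygosity** is `1 - p^2 - (1-p)^2` from the mode-level
frequency, averaged per window.

**Pooled Tajima's D.** Sites are reduced to a uniform sample size by drawing
`target = 30` reads without replacement (hypergeometric counts); sites below
30 or above `max = 360` reads are excluded. The classical
`D = (theta_pi - theta_W)/sqrt(V)` is then evaluated at `n = 30` with the
standard variance coefficients, treating alleles with subsampled count below
`min_count = 2` as absent. This subsample-then-classical construction is a
deliberate simplification of the cited pooled implementation, which derives
bias-corrected estimators for the read-resampling process. Two consequences
are documented rather than hidden: (i) trimming singletons shifts classical D
upward by a roughly constant amount, and (ii) reads resample a finite pool of
chromosomes, which distorts the sample spectrum. Absolute pooled D values are
therefore shifted (the simulated neutral background sits near +1.2 rather
than 0), but the scan only interprets D *relative* to the genome background —
the candidate-versus-rest and mode-versus-mode contrasts — where the shift
cancels. The estimator itself is exact for its inputs: on samples drawn
directly from the neutral frequency spectrum with all classes retained, its
windowed mean is centred at zero (tested), and it matches a brute-force
genotype-matrix oracle site for site.

**Fay & Wu's H.** Sites are polarized against the outgroup base: the derived
allele is the one the outgroup lacks; sites where the outgroup matches
neither allele, or is N, are skipped. `H = theta_pi - theta_H` with
`theta_H = sum 2k^2 / (n(n-1))` over derived counts `k` at uniform `n`.
Sites whose minor allele count is at most `nolowfreq = 3` are excluded
entirely — the guard matters doubly here, because a mispolarized
low-frequency site masquerades as a high-frequency derived allele and drags H
strongly negative (with 1% outgroup divergence roughly one site in 300 is
mispolarized). Depth bounds of `[4, 180]` apply before subsampling. H is
reported unnormalized, matching the original statistic; variance
normalization is available as an option.

## Candidate-region delimitation

The original call was explicitly arbitrary; `poolscan` codifies a
reproducible surrogate: maximal runs of overlapping sliding windows with mean
F_ST at or above 0.25 are merged; when an externally computed per-SNP
association score table is supplied (e.g. a structure-corrected contrast
statistic, with the threshold of 60 used in the source analyses), a run must
contain at least `min_assoc` SNPs above the threshold to survive; and the
boundaries are trimmed to the outermost SNPs with F_ST above 0.5. The rule is
deterministic, order-invariant and ignores NA windows; it is not claimed to
reproduce the published region coordinates on real data. Computing the
association score itself (an MCMC population model) is out of scope — the
scan consumes it as a TSV.

The depth-ratio scan normalizes each mode's per-position depth by that mode's
genome-wide mean, then averages `OP/(OP + CP)` over 2-kb windows: 0.5 means
equal copy number, 1/3 a halved OP copy number, 0 an OP-specific deletion.

Candidate-versus-rest contrasts use the two-sided Mann-Whitney test on
100-kb windows (exact for small samples via `stats::wilcox.test`, normal
approximation otherwise; fully tied inputs return p = 1 by convention), and
mode-versus-mode contrasts the paired two-sided Wilcoxon test. Physically
linked windows are not independent, a caveat inherited from the original
design.

## Divergence dating

Per-year mutation rates are composed from per-generation rates with
`n_gen = 15` generations per year: `mu_op = n_gen * mu_parth` for a lineage
that is parthenogenetic year-round, and
`mu_cp = (n_gen - 1) * mu_parth + mu_sex` for one sexual generation a year.
Defaults are the mutation-accumulation estimate for the pea aphid
(`mu_parth = 2.7e-10`, 95% CI 1.9--3.5e-10 per site per parthenogenetic
generation) and the insect consensus per sexual generation
(`mu_sex = 2.96e-9`, CI 1.52--4.99e-9). The rate separating the two allelic
classes is the mean of `mu_op` and `mu_cp` (5.395e-9/site/year at the
defaults); CI bounds are composed by pushing the bound values through the
same formulas.

Three estimators date the *op*/*cp* split:

1. **Net divergence:** `T = D_a / (2 mu)` with
   `D_a = D_xy - (pi_op + pi_cp)/2` computed from pooled frequencies over
   callable sites, without pool-size correction (the cited computation's
   details live in an external reference; this plain form is the package's
   documented choice). Assumes no selection on diversity within classes.
2. **Substitution counts:** haploid consensus sequences are drawn per mode —
   at every polymorphic site one allele with probability equal to its
   frequency — substitutions are counted on the callable mask, and
   `T = N_mutated / (2 N_sites mu)`. The draw is repeated 100 times; the
   point estimate uses the replicate mean and the combined CI takes the
   conservative product of extremes (low count with high rate against high
   count with low rate), with the count-only and rate-only intervals also
   reported, since the combination rule is not stated in the source.
3. **Calibrated dS:** coding sequences are extracted from the same consensus
   replicates, per-gene synonymous divergence is computed by NG86 counting
   with Jukes-Cantor correction, and the median over the region's genes is
   scaled through a fixed interspecies calibration (dS = 0.2268 at 22 My for
   the pea aphid versus the peach-potato aphid): `T = dS / dS_cal * T_cal`.

NG86 conventions: synonymous sites per codon count the fraction of
single-base changes preserving the amino acid, with changes to stop codons
nonsynonymous; multi-position codon differences average over mutational
pathways, excluding paths through stop codons unless every path is excluded;
a terminal stop codon is trimmed and a premature stop skips the gene with a
warning. The pathway table is verified against an independent brute-force
enumeration over all sense-codon pairs. An LWL85-style alternative
(delegating to `seqinr::kaks`) is exposed as an option.

## The synthetic-data generator

`truth_config()`/`build_truth()` draw a ground-truth frequency landscape and
`sample_pools()` samples sequencing from it in two stages — first the finite
pool of `2 * n_lineages` chromosomes (shared by the replicate libraries of a
population, as the replicates share the DNA pool), then reads, binomially at
Poisson depth. The two-stage design exists so the pool-size corrections in
the estimators have something real to correct.

Defaults emulate the study design this package reimplements: 3 + 3
populations with pools of 20--21 (CP) and 14 (OP) lineages, two libraries per
population at ~17x, background between-mode F_ST of 0.025, one candidate
interval at F_ST 0.35 with OP heterozygosity 0.14, an outgroup diverged 1%,
30 genes in the candidate interval, and a SNP density of 0.01/bp (the
called-SNP density of the source data; it also gives the candidate region a
between-class divergence near 0.5% per site, the magnitude the dS estimator
must resolve). The genome itself is desk-scale: 4 chromosomes of 2 Mb with a
200-kb candidate interval.

Background sites take a mean frequency from a neutral 1/i spectrum truncated
at a 30-class grid, and the two modes are displaced symmetrically by
`sqrt(F p (1-p))` so the per-site Nei F_ST equals the background target
exactly where feasible. Candidate sites place OP near fixation at the
frequency implying the target OP heterozygosity and solve for the CP
frequency that yields the target per-site F_ST exactly, with a random allele
flip per site. Within-mode differentiation defaults to zero (the source
reports none) but is exposed as a Balding-Nichols parameter.

What the generator does **not** emulate: linkage disequilibrium and haplotype
structure (sites are independent given the landscape), read-level errors and
mapping artifacts, indels, recombination-rate variation, and any real
coalescent history inside the candidate region — the "true" divergence time
of the simulated alleles is therefore not defined, and dating tests validate
arithmetic, expectations, and recovery under an explicit Jukes-Cantor
simulation rather than the landscape generator. Passing tests consequently
demonstrate correctness of the estimators and pipeline logic under the stated
sampling model, not robustness to the full messiness of real Pool-seq data.

## Numerical choices and degenerate inputs

- Window starts are `0, step, 2*step, ...`; only fully contained windows are
  kept. Windows with no usable SNPs yield NA statistics, never errors.
- F_ST is NA where the total heterozygosity is zero; depth-0 sites are NA
  under the corrected estimator.
- Tajima's D requires `n >= 4` (error otherwise) and returns NA for windows
  with no polymorphic site after `min_count` or with covered fraction below
  0.5; Fay & Wu's H returns NA when no polarizable site survives the guards.
- Allele-order ties in SNP calling break deterministically in sync column
  order (A, T, C, G).
- Every stochastic step (truth, sampling, subsampling, consensus draws) is
  reproducible from explicit seeds; the pipeline derives per-stage seeds from
  one master seed and reruns are byte-identical.
- Test problem sizes: most properties run on a 2 x 0.4 Mb genome;
  recovery-of-truth uses one 4-Mb chromosome (~2 x 10^4 SNPs); localization
  robustness uses 100 seeded 1-Mb runs; consensus expectations use 10^4 sites
  by 200 seeds. These sizes were chosen to estimate each quantity with
  standard errors well inside the asserted bounds.

## Known limitations

- Pooled D and H are reported on the shifted scale discussed above; compare
  them across windows, not against panel-sequencing values.
- The pool-corrected F_ST treats replicate-summed libraries as one binomial
  read draw, ignoring library-level overdispersion.
- Effect classification evaluates one variant at a time against the reference
  frame (no haplotype-aware compound effects), flags splice-adjacent sites
  within 2 bp of exon boundaries without subdividing them, and treats genes
  with broken reading frames as modifier-only.
- `N_sites` for dating defaults to the region width when no per-position
  depth mask is supplied; with real data the callable mask (depth >= 20 in
  every population) should be used.
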