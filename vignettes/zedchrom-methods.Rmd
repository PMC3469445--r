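---
title: "Methods: models, parameters, and design choices in zedchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in zedchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

zedchrom analyses three genome-wide assays around the histone variant H2A.Z
in plants — bisulfite methylomes, ChAP-seq enrichment, and allele-aware
RNA-seq — plus the association statistics that tie them together. This
vignette documents the statistical models, every tunable that matters, the
numerical conventions, and what the synthetic-data generator does and does
not emulate.

## Coordinates and gene models

All internal coordinates are 0-based, half-open (BED convention); GFF3
input (1-based, closed) is shifted on read. A gene model is a strand-aware
interval with a sorted, non-overlapping exon structure; transposons and
pseudogenes are one-exon models. Transcription-oriented offsets put offset
0 at the first transcribed base for the 5′ anchor (upstream strictly
negative) and at the first base past the gene for the 3′ anchor (the last
transcribed base is −1). This fixes an off-by-one that ends-aligned plots
otherwise leave ambiguous, and makes the minus strand an exact mirror image
of the plus strand — a property the test suite checks by brute-force
coordinate reversal. Overlapping gene models are all retained and each
contributes independently to metaplots; no de-duplication rule is imposed.

## Methylome model

A cytosine call carries a context (CG, CHG, CHH with H ∈ {A, C, T}, read
from the strand-appropriate trinucleotide) and methylated/unmethylated read
counts `c` and `t`. Every aggregate — metaplot bin, 50-bp window, locus
average — is the *weighted* level Σc/(Σc+Σt) of pooled counts, not a mean
of per-site fractions: pooling is robust at low coverage and matches how
replicate datasets are combined (counts summed before testing). Sites with
`c + t = 0` contribute nothing anywhere.

Metaplots align features at the 5′ or 3′ end and pool counts into fixed
bins of the signed offset; defaults are 2 kb upstream to 5 kb into the
feature at 100 bp for methylation, and 1 kb / 3 kb at 50 bp for
enrichment. Bins without coverage are `NA`, never zero.

Differential-methylation windows tile each chromosome from coordinate 0 in
non-overlapping 50-bp windows (the tiling origin is unstated in the field's
conventions; starting at 0 is deterministic and reproducible). Matched
mutant/WT windows are tested with a two-tailed Fisher exact test on the
pooled 2×2 count table; the two-tail is defined as the sum of
hypergeometric point probabilities ≤ that of the observed table (with a
1e-7 relative tie guard, the convention of `stats::fisher.test`, so the
enumeration oracle matches to < 1e-9). Windows with |Δ| < 0.10 in either
direction, or overlapping transposon annotations, are excluded — both
filters are absolute, and the suite asserts no reported window ever
violates them. Windows with zero coverage in either condition are skipped
and counted. No per-replicate dispersion model is fitted: replicates are
pooled by count summation, which is the procedure being re-implemented,
not a recommendation.

## ChAP enrichment model

Single-end 50-bp reads are converted to nucleosome midpoints by shifting
75 bp (half an average 150-bp nucleosome) from the read's 5′ end *in read
orientation*: `start + 75` on the plus strand, `end − 1 − 75` on the
minus strand. A `literal_start` flag reproduces the strand-naive reading
for comparison. IP and input midpoint densities are each scaled to counts
per million midpoints before base-wise subtraction — the subtraction is
meaningless for unequal library sizes otherwise; the scaling makes the
track invariant under library duplication (checked exactly).

Per-gene scores are means of per-base enrichment over three
transcription-oriented windows: TSS = [0, 500), body = [1 kb, L − 1 kb)
(defined only for genes ≥ 2.1 kb so the body window cannot touch the end
peaks), and sort-body = [500, L − 500) for heat-map ordering. Metaplots
omit, per gene, bases within 1 kb (configurable) of the end opposite the
anchor, so short genes do not fold their 5′ peak into the body average.

The nine-cluster partition computes low/mid/high terciles *independently*
on the TSS and body scores (marginal terciles — the clusters are therefore
only approximately equal-sized unless the two scores are near-independent),
with ties broken by gene id so the partition is deterministic; when n is
not divisible by 3 the lower tiers take the extra members. Pseudogenes are
removed from the lowest-enrichment category and grouped on their own.

## Allele-aware differential expression

The procedure distinguishes reads from the two parental ecotypes (WS and
Col) of a mosaic line:

1. **Scaffolds.** Each diagnostic SNP gets a pair of 75-bp scaffolds —
   the genomic window centred on the SNP with either allele substituted —
   differing only at the centre.
2. **Assignment.** Reads (and their reverse complements) are matched as
   exact substrings with no mismatch tolerance; a read counts for an
   ecotype only when it matches at an offset covering the centre base and
   does not match the other scaffold. Non-covering matches hit both
   scaffolds and are discarded as uninformative.
3. **Filters.** SNPs are kept when exonic in a gene > 200 bp, with ≥ 10
   assigned reads over all samples, and ≥ 36 bp (one read length) from
   both exon ends — a closer SNP cannot be covered at all offsets and its
   counts are biased. Distance is `min(pos − exon_start, exon_end − 1 − pos)`.
4. **Genotype structure.** Whether a region is homozygous WS, homozygous
   Col, or heterozygous is decided per *gene* from pooled counts over all
   samples of its retained SNPs (`Het` when the minor allele reaches 10%
   and ≥ 2 reads; thresholds robust to ~1% sequencing error at depths
   10–100, and configurable). Single-SNP, single-condition genotype calls
   at 10–20× depth miscall a true heterozygote a few percent of the time,
   which fragments the heterozygous runs and destabilises everything
   downstream; pooling to the gene level makes the structure call
   essentially error-free while per-condition information is preserved in
   the contributions (step 5). A line that truly is homozygous where the
   other is heterozygous shows up as a contribution near 0 or 1, not as a
   re-genotyping. Genes without retained SNPs inherit the nearest retained
   SNP's genotype within a 50-kb search radius (by gene midpoint, ties to
   the lower coordinate); genes with none are flagged unpartitionable and
   excluded.
5. **Contributions.** At heterozygous SNPs each condition's WS read-count
   contribution ws/(ws+col) is smoothed with a centred rolling mean over
   20 consecutive heterozygous SNPs (window spans indices i−9…i+10,
   truncated at block edges), restricted to contiguous heterozygous blocks
   so unrelated regions are never blended. Both conditions use the same
   linking SNP, chosen once, so a fold-change difference always reflects
   reads, not a different choice of locus.
6. **Partition and test.** Per-gene counts are partitioned: homozygous
   regions give all reads to their ecotype; heterozygous regions split by
   the smoothed contribution. The parts conserve the total exactly before
   rounding (asserted). Fold changes are computed on RPKM means with a 0.5
   RPKM pseudocount (zero-handling is otherwise undefined). For testing,
   counts are renormalized to the smallest library, summed over
   replicates, partitioned, rounded half-to-even, and each ecotype tested
   with the two-tailed Fisher exact test on the gene-vs-rest-of-library
   2×2 table — the table construction is isolated in `fisher_de_test()`
   so it can be swapped if a different reading is preferred. The library
   margin is `n_replicates x smallest library` per condition.
7. **Call.** Differentially expressed when either ecotype shows ≥ 2-fold
   change with p < 0.001, or both do in the same direction with
   p < 0.005; contradictory qualifying directions yield `none` with a
   flag.

No multiple-testing correction is applied — the procedure uses raw-p
thresholds by design, which we reproduce rather than improve. The exact
test is calibrated for counting noise; strong biological overdispersion
between replicates would inflate its false-positive rate (see
limitations).

## Association statistics

Spearman's rho uses average ranks for ties; its p-value is a seeded
permutation test (10,000 permutations by default, smallest attainable p =
1/(n+1)) since the field's software choice between permutation and
t-approximation is rarely stated. Box-plot summaries use type-7 quantiles
(linear interpolation of the empirical CDF, R's default) and Tukey 1.5×IQR
whiskers clamped to observed values. Fold-change direction at the ±0.5
log₂ threshold is strict. Set-overlap significance reuses the one Fisher
implementation. KDEs are exact Gaussian kernel sums (no FFT binning), so a
grid-point value equals the brute-force kernel sum to machine precision;
the default bandwidth is Silverman's rule.

## What the synthetic data emulates — and what it does not

The generators produce every input format the pipeline consumes, with
planted structure whose recovery the tests measure:

* **Genome and annotation**: random sequence; non-overlapping genes
  (default 300, 3–5 kb, 2–3 exons covering ~20% of the span — real
  transcripts concentrate RNA-seq reads over exonic SNPs, and intronless
  gene-sized transcripts would dilute SNP coverage below the 10-read
  filter at this sequencing scale), transposons, and pseudogenes.
* **Methylome**: per-cytosine depth Poisson around the nominal (default
  20×; 50× in the differential-window checks), methylated counts Binomial
  around the designed level — genic CG follows a piecewise-linear curve
  from 0.05 at the ends to 0.40 mid-body; TEs are high in all contexts
  with mutant CHG/CHH deltas of −0.10 emulating global TE
  hypomethylation; genic levels are unchanged in the mutant.
* **ChAP**: input midpoints uniform at 30/kb; IP adds a Gaussian TSS peak
  (σ = 100 bp at +250) and a body plateau with three clearly separated
  tier amplitudes per axis, assigned to genes in a balanced seeded way.
  Read intervals invert the midpoint rule exactly.
* **RNA-seq**: per-gene baselines Gamma-distributed (shape 4, mean 50
  reads), Negative-Binomial counts (size 100, i.e. ~10% extra-Poisson CV —
  mild, consistent with the exact-test framework being exercised), 30
  genes planted at 4-fold up, 36-mers drawn from transcripts carrying the
  block-appropriate allele over a shared WS/Het/Col block mosaic
  (contributions 0.3/0.5/0.7). Library sizes include a background of ~10×
  the genic reads, standing for the rest of the transcriptome: without it
  the planted genes inflate the mutant library enough that total-count
  normalization shifts every null gene by −0.3 log₂ — a composition
  artifact, not a property of the method.
* **Responsiveness**: Gaussian-copula draw targeting a rank correlation of
  0.33 with body enrichment (the copula's Pearson parameter is
  2·sin(πρ/6)), Gamma marginals, subscores as Dirichlet-like shares,
  housekeeping/hypervariable labels from the score quantiles.

Passing these tests shows the *computational procedure* is correct and
recovers planted structure at realistic desk-scale depths. It does not
show robustness to features the generator omits: sequencing error and
bisulfite conversion failure, alignment ambiguity and mapping bias,
overlapping and isoform-rich annotations, PCR duplicates, strong
biological overdispersion, or genomes large enough that memory-efficient
track storage matters.

## Problem sizes and numerical conventions

The test suite and acceptance script run, per quantity: all 123,201 2×2
tables with margins ≤ 25 against exhaustive enumeration; 200 genes at 20×
for metaplot recovery (±0.03 per bin); 120 genes at 50× with 60 planted
Δ = 0.30 windows for differential-methylation sensitivity (≥ 0.9) and null
rate (≤ 0.005); 270 genes at 30 midpoints/kb for nine-cluster recovery
(≥ 0.95); the full 300-gene, 3v3, mosaic condition for DE recall (≥ 0.9)
and false positives (≤ 1%); n = 5,000 for copula rho recovery (±0.05).
These sizes keep a complete run within a few minutes on one CPU while
leaving the binomial/Poisson error well inside each tolerance. Ties in
sorting are always broken by identifier; all simulation is seeded and
byte-identical on re-run (manifest checksums are compared, and a stage
whose inputs and parameters are unchanged is served from cache).

## Known limitations

* The Fisher exact DE test inherits the original procedure's assumptions:
  no dispersion modelling and raw-p thresholds. With strongly
  overdispersed replicates its false-positive rate will exceed the
  nominal level; a count-model DE method should be preferred for such
  data.
* Heterozygous-contribution smoothing assumes contributions are locally
  constant within a block; a recombination breakpoint between two
  retained SNPs blends the flanking regions over up to one window.
* Tracks are dense per-base vectors — simple and exact for genomes up to
  tens of megabases, not engineered for mammalian-scale data.
* Metaplots weight each read (pooled counts), not each gene; genes with
  deeper coverage influence a bin more. The alternative per-gene weighting
  is a one-line change in `ends_aligned_metaplot()` but is not what the
  pooled-count convention specifies.
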