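---
title: "Pooled heterozygosity sweep scans with poolsweep: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled heterozygosity sweep scans with poolsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
```

## The problem

In pool-seq studies of livestock populations, DNA from many animals of one
breed is sequenced as a single pool, and allele frequencies are estimated
from per-allele read depths rather than from individual genotypes. After
joint variant calling, the analysis questions are: which calls are reliable
(hard filtering and genotype-quality masking), which variants are new
relative to a reference catalogue, how variants distribute over functional
classes and over the genome, and where the genome shows the reduced
variability that marks a selective sweep. `poolsweep` implements this
post-calling pipeline end to end, together with a synthetic pool-seq
generator so that every stage can be exercised and validated without any
external data.

## Pooled heterozygosity and its Z-transform

For each SNP and pool, the read counts of the most and least abundant
alleles, $n_{MAJ}$ and $n_{MIN}$, are taken from the VCF allele depths (AD).
For a genomic window the pooled heterozygosity is

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}{(\Sigma n_{MAJ} + \Sigma n_{MIN})^2},$$

where the sums run over all SNPs in the window. $H_p$ lies in $[0, 0.5]$:
it is 0 exactly when no minor-allele reads are observed and 0.5 exactly when
major and minor read sums balance. Because the statistic is a function of
the windowed *sums*, it is insensitive to the per-site noise of low-coverage
pool-seq, which is the reason this estimator is preferred over per-site
heterozygosity averages in pooled data.

Window scores are standardised genome-wide,

$$ZH_p = \frac{H_p - \mu_{H_p}}{\sigma_{H_p}},$$

with $\mu_{H_p}$ and $\sigma_{H_p}$ the mean and standard deviation over all
scored windows of that pool. Strongly negative $ZH_p$ flags windows with an
excess of homozygosity. Windows are called at three tiers: candidate sweeps
at $ZH_p \le -4$, putative sweeps at $ZH_p \le -5$ and extreme sweeps at
$ZH_p \le -6$; overlapping or book-ended selected windows merge into
distinct loci (`call_sweeps()`).

Assumptions worth keeping in mind: the Z-transform treats the genome-wide
window population as a homogeneous background, so chromosome-scale
differences in diversity are absorbed into the tails; and read counts are
taken at face value, so mapping artefacts that survive the hard filters can
mimic homozygosity.

## Numerical and convention choices

* **Window scheme.** 150 kb windows stepping every 75 kb (50 % overlap),
  *full windows only*: starts run $0, 75\,000, \dots$ while
  $\mathrm{start} + 150\,000 \le L$. No truncated trailing window is
  emitted, so every window's $H_p$ is computed over the same width and every
  interior base is covered exactly twice. For the 29 UMD3.1 bovine autosomes
  (shipped as `umd31_autosomes()`) this yields 33,453 windows; keeping
  $\ge$ 75 kb truncated tails would instead give 33,482, and keeping every
  start 33,511. Published cattle scans rarely state their edge rule, and
  window totals reported for this assembly differ by a few dozen windows
  from any of these conventions, consistent with counting only windows
  actually scored in the data; the fixed full-window rule is used here
  because it is the only one that makes window width, and hence the
  $H_p$ null distribution, homogeneous.
* **Population standard deviation** (divisor $N$) for $\sigma_{H_p}$: the
  Z-transform is over the full population of genome windows, not a sample
  from it; with two windows the scores are then exactly $\pm 1$.
* **Unscored windows.** Windows with fewer than `min_snps` (default 10)
  SNPs carrying read support get no $H_p$ and are excluded from $\mu$,
  $\sigma$ and calling: with a handful of SNPs, $H_p$ is dominated by
  binomial read noise and its extreme values are meaningless. Setting
  `min_snps = 0` scores every window with at least one read. A scan with
  fewer than two scored windows, or with zero variance in $H_p$, is an
  error rather than a silent degenerate result.
* **Z-transform scope** is genome-wide per pool, not per chromosome, since
  each breed is screened against its own single genome-wide distribution.
* **Only SNP records** enter the scan; indels and records failing the hard
  filters are removed first.
* **Coordinates** are 0-based half-open for all windows and intervals
  (conversion to and from 1-based VCF positions happens once, at the
  container boundary), which keeps window arithmetic free of off-by-one
  cases; the tests pin the boundary behaviour (a variant at 1-based
  position 1,000,001 falls in the second 1 Mb window).

## Hard filtering

Records fail when any *present* metric violates its threshold with a strict
inequality: QUAL < 30, QD < 2, MQ < 40, FS > 60, HaplotypeScore > 13,
MQRankSum < −12.5, ReadPosRankSum < −8. Two deliberate choices:

* **Absent metrics never fail a record.** Callers omit site-class-dependent
  annotations (the rank sums need heterozygous support); treating absence
  as zero would silently discard valid sites.
* **Strictness.** Values exactly at a threshold pass, matching the
  conventional phrasing of the filter expressions.

The per-pool genotype-quality mask removes pool entries with GQ < 20
(GQ = 20 is kept); a record is retained while at least one pool survives.
Verdicts list every violated criterion, which makes filter behaviour
property-testable: tightening any single threshold can only shrink the pass
set, and relaxing exactly the violated criterion flips exactly that reason.

## Novelty, consequences, density

* **Variant keys.** Matching against the known-variant catalogue is
  allele-exact on normalised (chrom, pos, ref, alt) keys — the dbSNP
  convention — with a position-only mode behind a flag. Normalisation trims
  shared bases, leading side first (advancing the position), then trailing,
  always keeping at least one base per allele; e.g. `100:CA>CG` becomes
  `101:A>G` and `100:ATT>AT` becomes `101:TT>T`. Trimming both query and
  catalogue with the same deterministic rule makes equivalent indel
  representations collide without needing the reference sequence, which
  keeps the module self-contained; full left-alignment against a FASTA is
  intentionally out of scope.
* **Functional classes.** Annotator terms map deterministically onto a
  fixed class vocabulary; multi-annotated variants reduce to their single
  most severe class under a fixed severity order (stop gain > stop lost >
  essential splice > missense > synonymous > splice region > UTRs > miRNA >
  intronic > non-coding gene > up/downstream > intergenic), with an "all"
  mode that counts every annotation. The reduction is idempotent and
  independent of row order. Unknown terms land in an explicit `unmapped`
  bucket rather than being dropped.
* **Zygosity.** Within a pool a site is *fixed* (all ploidy alleles the
  same non-reference allele), *segregating* (two or more distinct alleles)
  or *reference*. The third class is needed because joint-called multi-pool
  VCFs contain pool-level non-variant rows; the first two alone only
  partition variant-in-pool sites.
* **Density scan.** 1 Mb non-overlapping windows, four categories (all,
  missense, loss-of-function = stop gain/lost, novel; categories are not
  exclusive), density normalised by true window length in kb so truncated
  terminal windows are not biased. The top 1 % takes
  $\lceil 0.01N \rceil$ windows with $N$ counting *all* windows (the
  simplest fixed denominator; a nonzero-only denominator is available),
  ties broken by genomic order. Genes are ascribed on $\ge$ 1 bp overlap of
  half-open intervals.
* **Headline proportions** are unweighted means of per-pool proportions,
  not ratios of pooled totals: multi-pool totals are unions, so the two
  differ. Reported proportions round half away from zero to 2 decimals.

## The synthetic generator

`simulate_poolseq()` emulates the study design the pipeline targets: three
breed pools of 30 diploids each (pool ploidy 60) at ~20x expected coverage
per pool, ~1 variant per 250 bp of which 11 % are indels, and a catalogue
containing 93 % of simulated variants. Specifically:

* variant positions are Poisson along each chromosome, with planted
  hotspots multiplying the local rate;
* each pool draws an alternate-allele copy count from the neutral
  spectrum $P(k) \propto 1/k$, $k = 1..59$ — the minimal frequency model
  under which the $ZH_p$ tails are meaningful; inside a planted sweep the
  minor-allele frequency is multiplied by $1 - \mathrm{het\_reduction}$.
  Sweeps compress frequencies instead of deleting variants so that SNP
  density stays flat and windowed heterozygosity, not SNP count, is the
  detecting signal;
* per-pool depth is Poisson, split binomially by the pool allele frequency
  into the AD field; SNP substitution types are drawn to give a
  transition/transversion ratio of 2.2, the genome-wide cattle value;
* INFO metrics come from pass-region distributions, after which
  `inject_filter_failures()` plants an exact count of filter-failing
  records (one violated criterion each), giving the filter tests a known
  ground truth;
* indels are emitted only so variant-type tables have content; they never
  enter the sweep scan;
* a single seed drives one RNG stream, so a fixed configuration is
  byte-reproducible.

What the generator does **not** model: linkage disequilibrium and coalescent
genealogy, sequencing error and mapping bias, per-breed allele-frequency
differences, and structural variation. Passing tests therefore demonstrate
that the statistics and their calling logic behave as specified on data
satisfying the stated model — not that the pipeline is robust to alignment
artefacts or demographic confounding in real pool-seq data.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: hand
arithmetic for the $H_p$ worked examples, brute-force window recomputation
from the flat per-SNP count list (about a thousand windows), enumeration
for substitution types and two-largest-depth selection, and binomial or
Poisson error bounds for the generator's rates. Sweep recovery is measured
on a 3-chromosome x 30 Mb genome with five planted 300 kb sweeps
(`het_reduction` 0.95) over 20 independent seeds, requiring at least 90 %
of planted sweeps to overlap a called candidate locus with at most one
false locus per genome on average; these sizes keep the whole suite at a
few minutes while leaving the per-window SNP counts (~600) representative
of real 150 kb windows at this variant density. The density hotspot check
uses a ~100 Mb genome at a reduced variant rate — reducing the rate makes
the detection *harder* (noisier window counts), so it does not flatter the
result.

## Known limitations

* Pool-level analyses assume the VCF's AD field is trustworthy; no
  re-genotyping is attempted.
* Catalogue matching without a reference sequence cannot left-align indels
  through repeat runs longer than the shared-base trim; two representations
  anchored at different repeat copies will not collide.
* The scan has no significance machinery beyond the Z-score tiers
  (no permutation or FDR); tier thresholds are conventions, not p-values.
* Multiallelic sites contribute their two largest allele depths to
  $H_p$; third alleles are ignored by the statistic.
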