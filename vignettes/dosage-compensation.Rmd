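---
title: "Detecting sex-linked SNPs and dosage compensation from RNA-seq allele depths"
author: "sexlinkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-linked SNPs and dosage compensation from RNA-seq allele depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlinkr)
```

## The problem

In a species with young XY sex chromosomes, X- and Y-linked gene copies
(gametologs) still align to the same transcript contigs, so RNA-seq of a
family can reveal them through segregation alone.  At a genuinely
sex-linked SNP, every male carries one X and one Y allele and is therefore
heterozygous, while every female carries two X alleles and is homozygous
— and for the *same* allele, since in a ten-generation sib-mated line the
X haplotypes are (nearly) fixed.  Residual autosomal heterozygosity is
low in such a line, so this pattern concentrates almost exclusively at
X/Y sites.

Once sex-linked SNPs are known, the allele depths at exactly those
positions give allele-specific expression of the X and the Y copy,
cleanly separated, and two ratios summarize the biology:

* **Y/X in males** — reduced Y expression (Y/X < 1) is the expression
  signature of Y degeneration;
* **Xmale/2Xfemale** — expression of the single male X over both female
  X copies.  Without dosage compensation this is 0.5 (one copy vs two);
  a mechanism that boosts male X expression pushes it toward 1.

The package implements this whole chain — detection, quantification,
ratio analysis and hypothesis tests — plus a synthetic-data generator
with ground truth that makes every stage testable without sequencing
data.

## Detection model

Female genotypes are taken verbatim from the VCF genotype field: a
diploid caller is reliable when both alleles are expressed at comparable
levels, which is the case for the two female X copies.  Male genotypes
are *not* trusted: a diploid caller assumes balanced allelic expression,
and a weakly expressed Y allele makes a heterozygous male look
homozygous.  Males are therefore re-genotyped from the allele depths
(`infer_male_genotype()`), by default calling heterozygosity as soon as
each allele has at least **one** supporting read (`min_y_reads = 1`,
`min_minor_fraction = 0`).  This is deliberately permissive so weakly
expressed Y alleles are not discarded; the cost, false heterozygotes from
sequencing errors, is controlled downstream (see the false-positive
analysis).  A binomial alternative (`male_rule = "binomial"`) rejects
homozygosity only when the minor depth is improbable under a per-read
error rate; it is stricter at high depth and provided for sensitivity
analysis.  Equal depths still count as heterozygous: the rule is
support-based, not ratio-based.

A site is classified sex-linked when all males are heterozygous and all
females homozygous for the same allele; that shared allele is the X
allele, the other the Y allele.  Any individual missing at a site
disqualifies the site (not the contig) — the pattern is defined over
*all* individuals, and per-site disqualification keeps the most usable
data.  A contig with at least one sex-linked SNP is called sex-linked;
`passes_strict` marks contigs with at least two, a subset with a far
lower false-positive rate.  A consequence of requiring Y-supporting
reads in every male is that a fully silent Y is undetectable: no
detected contig can have Y/X = 0.

On sex-linked contigs the remaining sites are screened for X-linked
polymorphism (`detect_x_polymorphism()`): a heterozygous female, a
heterozygous male at a non-sex-linked site, or all individuals
homozygous but not for the same allele.  Expressed female
heterozygosity is what discriminates dosage-compensation mechanisms: an
X-inactivation-like mechanism silences one female copy and hides it.

## Expression model

Reads are counted at the sex-linked SNP positions only, never over the
whole contig, so X and Y reads cannot mix.  For each contig and
individual, the allele-class sum *r* (male X, male Y, or both female X
copies) is normalized as

$$E = \frac{r}{n \cdot l}$$

with *n* the number of sex-linked SNPs of the contig and *l* the
normalized library size in millions of reads.  *l* subtracts rRNA,
mitochondrial, chloroplast and transposable-element reads from the total
mapped reads, because these fractions differ systematically between
sexes and between sequencing runs and would otherwise masquerade as
expression differences.  (Subtraction is one of two defensible readings
of "normalized to take these categories into account"; a
rescale-per-category scheme is deliberately out of scope.)  An
RPKM-style variant divides *r* by contig length (kb) and raw total
mapped reads (millions); it is used for the binned dosage profiles,
while the ratio analyses use *E*.

Expression is summarized across individuals of a sex *before* ratios
are formed (mean by default, `summary_stat = "median"` available), and
the ratio of summaries is reported; a per-individual-ratio mode
(`ratio_mode = "per_individual"`) exists for sensitivity analysis.
Ratio-of-means estimators carry a small positive finite-sample bias of
order the squared coefficient of variation of the denominator; at the
default simulation depths this is below one percent and medians over
contigs are essentially unaffected.

## Dosage analysis

Per contig, `compute_dosage_records()` forms Y/X and Xmale/2Xfemale,
bins Y/X into the half-open intervals
`[0,0.25) [0.25,0.5) [0.5,0.75) [0.75,1) [1,1.5) [1.5,Inf)`, and flags
contigs with Y/X strictly above 1.5 or Xmale/2Xfemale strictly above 2
(equality retained).  Such male-biased patterns suggest sexually
antagonistic expression, for which no dosage compensation is expected;
they are excluded from the dosage profile.  Y degeneration is tested
with a paired two-sided Wilcoxon signed-rank test of X vs Y summaries
within contigs, reported with its direction (the one-sided version is a
flag away); departure of Xmale/2Xfemale from 0.5 uses the one-sample
Wilcoxon.  Degenerate inputs (all differences zero) return a p of 1
rather than an error.

`build_dosage_profile()` reports, per Y/X bin, medians over all
(contig, individual) pairs of the same sex for XX females, X males and
Y males, rescaled by the female value so XX females are 1 in every bin.
The male X+Y bin value is defined as the sum of the X and Y bin values,
so the conservation identity XY = X + Y holds exactly at the bin level
(the alternative — the median of per-contig X+Y sums — differs
negligibly within a Y/X bin, where Y is roughly proportional to X, and
would not satisfy the identity).  Confidence intervals are percentile
bootstrap over contigs (default 1000 resamples, seedable); each
replicate is rescaled by its own female median, so the reference class
has a degenerate interval.  The bootstrap unit is the contig because
contigs, not individuals, are the exchangeable replicates of the
evolutionary question.

`heterozygosity_comparison()` partitions sex-linked contigs into a
compensated stratum (default Y/X < 0.5 and Xmale/2Xfemale ≥ 0.75 —
there is no canonical published definition, so the thresholds are
configurable) and its complement, cross-tabulates expressed X
polymorphism, and compares proportions with Fisher's exact test.

## The synthetic-data generator

`simulate_dataset()` emulates the study design the analysis assumes: 3
males and 3 females from a deeply inbred line (defaults), sequenced in
two run batches (one male and one female in run 1), with library
composition differing by batch (rRNA) and sex (chloroplast, TE).  Its
parameters are the study conditions, not tuning dials:

* **Baseline depth.** `depth_mean = 50` is the expected total site depth
  for a two-copy genotype in an average library; one expressed copy has
  baseline `b = depth_mean/2`.  Depths are negative-binomial with size
  `depth_dispersion = 10` (about 32% extra-Poisson CV per site, a
  moderate RNA-seq overdispersion) and are scaled per individual by
  nuclear library size, so the `E` normalization is genuinely exercised.
* **Degeneration and compensation.** Each sex-linked contig draws a
  coefficient `d`; a male expresses X at `c·b` and Y at `d·c·b`, so the
  observed Y/X ratio estimates `d` in every mode.  The default sampler
  is log-normal with median 0.77 and sdlog 0.5, centred on the observed
  degree of Y expression reduction in a young plant XY system and wide
  enough to populate all Y/X bins.  The compensation factor is `c = 1`
  (none; Xmale/2Xfemale expectation 0.5), `c = 2` (full; the single male
  X matches both female copies, expectation 1.0), or `c = 2/(1+d)`
  (proportional, the default; total male X+Y output equals total female
  output, the pattern actually observed when compensation tracks
  degeneration).
* **Inbreeding.** Autosomal sites are heterozygous in a given individual
  with probability `h = 0.05`, a plausible residue after ten generations
  of sib mating; homozygotes pick either allele with probability 1/2
  independently per individual.  A single parameter replaces pedigree
  simulation because only genotype-pattern frequencies matter: the
  probability that an autosomal site shows the sex-linked pattern in
  truth is `h^3 (1-h)^3 / 4` for 3+3 individuals, and the generator is
  tested against that closed form.
* **Errors.** Every read is mis-assigned to the other allele with
  probability `e = 0.001` (about Q30).  Genotype columns are produced by
  a small depth-based caller (heterozygous iff both alleles have ≥ 2
  reads and ≥ 10% minor fraction), emulating what an upstream caller
  sees in the RNA reads — in particular, monoallelic expression hides
  true heterozygosity from it, which the X-inactivation scenario
  (`x_inactivation`) relies on: there, every female silences the *same*
  X haplotype chromosome-wide, the configuration a heterozygosity
  contrast is designed to detect.

What the generator does **not** model: read sequences (no FASTQ),
assembly artifacts such as chimeric X/Y contigs, paralogous mapping,
allele-specific mapping bias, and positional effects along contigs.
Passing tests therefore validate the statistical logic of the pipeline,
not robustness to mis-assembly or mapping artifacts, which on real data
are handled upstream.

## Validation and numerical choices

The test suite establishes, among other properties:

* the site classifier agrees with brute-force enumeration over all
  3^6 = 729 genotype configurations for 3 males + 3 females (exactly two
  configurations are sex-linked) and on randomized error-free inputs;
* a clean null (`h = 0`, `e = 0`) yields exactly zero sex-linked calls
  across 10,000 autosomal contigs;
* with no compensation and `d = 1` the median Xmale/2Xfemale over 500
  simulated contigs is 0.5 ± 0.05; with full compensation and `d`
  uniform in [0.1, 0.5) it is 1.0 ± 0.05;
* under a realistic null (`h = 0.05`, `e = 0.005`, depth 50) the strict
  (≥ 2 SNP) false-positive rate over 50,000 autosomal contigs is at most
  0.001 — the permissive 1-read male rule is affordable because
  requiring a second sex-linked SNP crushes the per-contig error rate;
* simulated `d` is recovered by the Y/X ratio with Spearman correlation
  above 0.9 (500 contigs, depth 100);
* identical seeds give byte-identical VCFs and reports.  The simulator
  isolates its RNG state, and reports contain no timestamps for exactly
  this reason (run metadata lives on the fitted object instead).

Problem sizes in the routine test run (hundreds of contigs for
calibration checks, 10,000 per null replicate) were chosen so that
Monte-Carlo error is several times smaller than each asserted tolerance.

## A worked example

```{r example}
cfg <- sim_config(n_sexlinked = 200, n_autosomal = 200, seed = 5)
sim <- simulate_dataset(cfg)
fit <- sexlink(sim)
summary(fit)
```

```{r profile}
prof <- build_dosage_profile(fit, n_boot = 200, seed = 1)
prof
```

```{r figures, fig.width = 7, fig.height = 4}
oldpar <- par(mfrow = c(1, 2)); plot(fit); par(oldpar)
plot(prof)
```

Under the default proportional compensation the profile shows male X
rising toward the female level as Y/X falls while male X+Y stays at the
female level throughout — the signature that distinguishes dosage
compensation from sexually antagonistic expression, which would move
male and female totals apart.

## Known limitations

* Detection requires expressed Y alleles; hemizygous genes (no Y copy)
  are invisible by construction, and weakly expressed sex-linked genes
  are under-detected — the method's false-*negative* rate is driven by
  coverage.
* With three individuals per sex the segregation filter cannot
  distinguish sex linkage from an autosomal site that mimics the
  pattern by chance; the simulation-based false-positive estimate is
  the quantitative guard, and the ≥ 2-SNP set the conservative choice.
* The library-size correction assumes the category read counts (rRNA,
  organellar, TE) are supplied; errors there propagate directly into
  between-sex ratios.
* Wilcoxon p-values at thousands of contigs are astronomically small
  and should be read as "strongly inconsistent with symmetry", not as
  effect sizes; the medians and profiles carry the scientific content.
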