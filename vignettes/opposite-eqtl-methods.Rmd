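---
title: "Detecting tissue-discordant (opposite) cis-eQTL effects: methods and design"
author: "oppeqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting tissue-discordant (opposite) cis-eQTL effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oppeqtl)
```

## The problem

A cis-eQTL is a genetic variant associated with the expression of a nearby
gene (here, within 1 Mb of its transcription start site, TSS). Most genes
with an eQTL have one in several tissues, and usually the allele that raises
expression in one tissue raises it in the others. The interesting exception
is the *opposite* eQTL effect: the same variant-gene pair shows a
significant association in two tissues with reversed sign of the slope
$\beta$. Such reversals mark tissue-specific rewiring of regulation and are
a useful annotation when interpreting GWAS loci, because a trait mediated by
several tissues can respond to one variant in conflicting directions.

Calling a reversal from summary statistics is delicate for two reasons.
First, the most significant SNP ("top eQTL SNP") for a gene differs between
tissues, so the comparison must be made between top SNPs that are identical
or in strong linkage disequilibrium (LD) — otherwise one compares
independent signals (e.g. a primary signal in one tissue against a secondary,
marginal signal in the other), which says little about regulation of the
same functional variant. Second, "not significant" must not be confused
with "opposite": the procedure below treats a missing cross-tissue beta as
zero, which satisfies the opposite-direction inequality but never by itself
creates an eligible comparison.

## The classification procedure

The pipeline consumes per-tissue tables of *significant* variant-gene
associations (gene id, variant key, rsid, slope $\beta$, nominal p, signed
TSS distance). Significance is extensional: a pair is significant in a
tissue iff it appears in that tissue's table; no threshold is re-derived.
For every gene and tissue the top eQTL SNP is the record with minimal p,
ties broken by the byte-wise smallest rsid string (so `"rs10" < "rs2"`);
this mirrors a plain lexicographic sort of ID strings. Indels, multi-allelic
variants and variants absent from the reference haplotype panel are removed
before any LD work.

For a gene $g$ and an unordered tissue pair $(x, y)$, let SNP-$x$ and
SNP-$y$ be the top SNPs of $g$ in each tissue and let $\beta_{ij}$ denote
the effect of SNP-$i$ in tissue $j$, with $0$ encoding "not significant in
that tissue". The 2x2 analysis table $(\beta_{xx}, \beta_{xy}, \beta_{yx},
\beta_{yy})$ is classified as:

* **ineligible** if $\beta_{xx} = 0$ or $\beta_{yy} = 0$ (the gene lacks a
  signal in one tissue);
* **eligible** iff SNP-$x$ = SNP-$y$, or at least one of them is significant
  in both tissues ($\beta_{xy} \neq 0$ or $\beta_{yx} \neq 0$);
* **opposite** iff $\beta_{xx}\beta_{xy} \le 0$ and
  $\beta_{yx}\beta_{yy} \le 0$, otherwise **same**;
* crossed with LD: $r^2 > 0.8$ (strictly; $r^2 = 1$ for identical SNPs)
  gives groups **1a** (opposite) / **2a** (same), and $r^2 \le 0.8$ gives
  **1b** / **2b**. An undefined $r^2$ (monomorphic SNP) counts as not in LD.

Genes and top SNPs appearing in at least one 1a or 2a table are the
*multi-eQTL* sets (top signal shared across tissues); those in at least one
1a table are the *opp-multi-eQTL* sets. Both SNP-$x$ and SNP-$y$ of a
qualifying table enter the SNP sets, and every qualifying tissue pair is
kept as evidence so per-tissue counts can be recomputed later. By
construction opp $\subseteq$ multi $\subseteq$ all, for genes and SNPs alike.
For $n$ tissues there are $n(n-1)/2$ tissue pairs (1128 for 48) and one
table per gene and pair.

$r^2$ is computed from a phased biallelic reference panel by direct
frequency counting: with alt-allele frequencies $p_A$, $p_B$ and haplotype
frequency $p_{AB}$,
$r^2 = (p_{AB} - p_A p_B)^2 / \big(p_A(1-p_A)\,p_B(1-p_B)\big)$,
which equals the squared Pearson correlation of the two 0/1 haplotype
vectors. No EM estimation is needed because the panel is phased; this is
exact and deterministic. Set queries scan partners within a 1 Mb window — a
plumbing bound that is never binding for cis analysis.

## Enrichment analyses and their nulls

**TSS proximity.** The statistic is the Pearson (non-excess) sample
kurtosis $m_4/m_2^2$ of the raw signed TSS distances of a SNP class. On a
window-limited sample, mass concentrated at the TSS with sparse far-flung
points is leptokurtic, so higher kurtosis means more TSS-peaked; the test is
one-sided in that direction, matching the enrichment hypothesis. We chose
the kurtosis of the raw sample rather than of a density estimate because it
is well defined and bandwidth-free. Because SNPs shared by more tissues sit
closer to the TSS regardless of direction, the null is *sharing-matched*:
each replicate draws, per sharing-count stratum, as many multi pairs
(without replacement) as the opp class has in that stratum. The p-value is
the fraction of replicates with kurtosis at least the observed; when no
replicate reaches it, the strict bound $p < 1/n_\text{rep}$ is reported
rather than zero. A descriptive density ratio at the TSS is also provided:
Gaussian KDEs (Silverman bandwidth, recorded in the output) of two distance
samples evaluated at 0.

**Epigenetic annotations.** Boolean annotations (H3K4me1, H3K4me3, H3K9ac,
H3K27ac, DNase) per SNP and cell line, with an availability mask per
(cell, mark). The statistic is the mean, over available cell lines, of the
per-cell fraction of annotated SNPs. Because TSS proximity itself predicts
active-chromatin marks, the null here is *TSS-distance-matched*: the signed
distance axis is cut into half-open 1-kb windows spanning the +/-1 Mb cis
range, and each replicate samples per window as many multi pairs as the opp
class has there. Window deficits are capped at availability and logged,
never filled by sampling with replacement, which would duplicate SNPs and
distort fractions. The 95% CI is the empirical 2.5/97.5 percentile of the
replicate means.

**GWAS-catalog LD overlap.** Catalog rows are filtered at reported
$p < 5\times10^{-8}$ (strictly), multi-trait duplicates collapsed to the
minimum p, trait identity ignored. A class SNP "overlaps" if its $r^2$ with
at least one GWAS SNP exceeds 0.8, membership itself counting via self-LD.
Catalog rsids absent from the panel stay in the set but can only match by
identity (logged). Class-vs-class comparison uses a two-sided Fisher exact
test (conditional-MLE odds ratio, as reported by `fisher.test`); the
sidedness is the conventional default since nothing in the procedure fixes
a direction for that contrast. The opp-vs-adjusted-multi comparison reuses
the TSS-distance-matched resampling null; per-SNP hit status is precomputed
once since it depends only on the SNP.

All resampling flows from one master seed through a counter-based derived
seed per replicate, so replicates are reproducible and order-independent,
and the two enrichment analyses can share a generator without interference.

## Locus views

For one gene and tissue pair, all tested SNPs (including non-significant
ones) within 1 Mb of the TSS are harmonized so the anchor tissue's betas are
non-negative: whenever $\beta_\text{anchor} < 0$ the ref/alt assignment of
that SNP is conceptually swapped, negating both tissues' betas together.
This is an involution and leaves every sign product — hence every direction
call — unchanged. SNPs untested in the anchor tissue are left unflipped.

## The synthetic cohort generator

Real inputs at full scale are tens of gigabytes; the generator emulates
their statistical structure with planted ground truth so every stage is
testable offline. Its defaults are the package's study conditions:

* **Panel**: 120 LD blocks of 6 SNPs, 200 phased haplotypes. Within a
  block every SNP copies a common core indicator (an ancestral pair at
  frequency drawn in [0.3, 0.7]) with a per-SNP flip rate solved, from the
  closed-form expectation, to hit a within-block $r^2$ target of 0.9;
  blocks sit megabases apart, so cross-block $r^2$ is at the independence
  level $\approx 1/(\text{haplotypes}-1)$. Allele frequencies are kept in
  [0.05, 0.95].
* **Effects**: 200 genes over 6 tissues. Each gene takes one causal block
  and SNP, $|\beta| \sim$ log-normal(log 0.5, 0.35), and a
  truncated-geometric number of active tissues (p = 0.35). A fraction
  theta_opp = 0.1 of genes is planted "opposite": one designated active
  tissue flips the sign. The reversal always sits on the causal SNP's own
  block, so the high-LD group (1a) is reachable by construction. LD partners
  enter a tissue's significant table with $\beta$ attenuated by the signed
  haplotype correlation $r$ when they pass a logistic detection model in
  scaled $|\beta|$ (slope 8, midpoint 0.25, per-tissue scale in [0.9, 1.6]
  standing in for sample size); causal records are always detected unless a
  nonzero causal-drop rate is configured. p-values are a deterministic
  monotone-decreasing map of scaled $|\beta|$ — the pipeline only consumes
  summary statistics, and monotonicity is the only property top-SNP
  extraction needs, so no genotype-level regression is simulated.
* **TSS distances** are a mixture of a uniform background over the +/-1 Mb
  cis window (weight 0.35) and a Laplace peak at the TSS (scale 20 kb);
  planted opposite genes get a sharper, heavier peak (weight 0.9, scale
  5 kb). A pure Laplace at two scales would be invisible to kurtosis, which
  is scale-invariant: it is the window-limited background that makes
  peakedness measurable, and real eQTL TSS-distance distributions do show
  exactly this sharp-peak-plus-broad-background shape.
* **Annotations**: Bernoulli presence at background rate 0.2, additively
  boosted by 0.3 for SNPs on planted opposite blocks ($|r| > 0.8$ to the
  causal SNP), over 12 cell lines with an 0.85 availability rate.
* **GWAS catalog**: for each planted opposite gene, with probability
  rho = 0.3 an LD partner of its causal SNP (verified $r^2 > 0.8$ in the
  panel) is emitted below $5\times10^{-8}$; 20 background associations land
  on random panel SNPs and a few sub-threshold rows exercise the filter.
  These rates put the class overlap proportions in the 10–30% range typical
  of eQTL SNP classes, with the opp class clearly above the multi class.

Everything the generator writes (per-tissue TSVs, panel VCF, annotation TSV,
catalog TSV, ground-truth JSON) re-loads through the package's own readers,
and repeated runs under one seed are byte-identical.

### What the generator does not emulate

No coalescent realism (recombination gradients, allele-frequency spectra),
no covariate or expression-level structure, no multi-ancestry panels, no
correlated annotations between marks or cells, and LD confined to disjoint
blocks. Consequently, passing tests demonstrate that the procedure recovers
what it defines — planted reversals, planted TSS/annotation/GWAS enrichment
— under clean LD structure; they do not certify behavior under the partial,
overlapping LD and pervasive confounding of real data.

## Numerical and design choices

* Slopes of exactly 0 are rejected at load so that 0 unambiguously encodes
  "not significant"; real slope estimates are never exactly 0.
* The LD threshold is strict (`>`), including at $r^2$ exactly 0.8, and the
  GWAS p filter is strict (`<`) at $5\times10^{-8}$.
* Coordinates are 1-based GRCh37; TSS distances are taken verbatim from the
  input and never recomputed, so no gene model is required.
* Tie-breaking by byte-wise rsid order is locale-independent (C collation).
  Only the designated tie winner is ever used as SNP-x; when tied top SNPs
  are in perfect LD the direction call is unaffected.
* Tissue clustering uses complete linkage on Euclidean distances between
  rows of the opposite-fraction matrix — the conventional heatmap default;
  the linkage is an argument, so it is overridable. Undefined fractions
  (tissue pairs sharing no records) are NA, imputed by column means with a
  warning before clustering only.
* The opposite-fraction unit of sharing is the (gene, SNP) record, not the
  bare SNP: one SNP can regulate several genes with different signs, so
  "opposite" is only well defined per gene-SNP pair.
* The p-value deviation histograms use a fixed grid (0.25 bins on
  $-\log_{10} p \in [0, 30]$, overflow clipped into the last bin) so that
  the multi and opp densities and their difference are always comparable.
* The coefficient of variation uses the sample (n-1) standard deviation.
* Resampling CIs are empirical percentiles; zero-exceedance p-values are
  reported as the strict bound $p < 1/n_\text{rep}$, never as 0 alone.

## Problem sizes used in the shipped analyses

The default cohort (200 genes x 6 tissues, 200 haplotypes) is the unit of
the worked examples and of the acceptance script, with 10,000 resampling
replicates for each enrichment test. The classifier-equivalence and
planted-recovery checks run on that cohort; the planted-enrichment checks
use a 1,500-gene cohort with theta_opp = 0.1, a sharpened TSS peak
(scale 1.5 kb, background 0.08) and an annotation boost of 0.4, at 1,000
replicates — the opp class must stay a small fraction of the multi class,
otherwise the matched null keeps re-drawing the planted pairs themselves
and the test loses power by construction. Null-calibration checks use 50
seeded runs at 200 replicates.

## Known limitations

* With small opp classes (tens of pairs) the kurtosis statistic is noisy;
  the enrichment p is then properly conservative rather than powerful.
* Sharing- and TSS-matched subsampling cap at stratum availability; heavy
  deficits (logged) shrink the adjusted set below the opp class size and
  weaken the null's match.
* The structural sensitivity of GWAS overlap to removing the LD gate has,
  in the generator, the opposite sign to real data: synthetic low-LD
  opposite cases arise from censoring of the causal record and so share the
  causal block's planted GWAS partners, whereas in real data gate-failing
  discordances are dominated by independent secondary signals with weaker
  trait relevance. The gate's set-theoretic behavior (strict growth when
  removed) is unaffected.
* Undefined $r^2$ (monomorphic in the panel) maps to "not in LD" — the
  behavior of standard LD tools that omit such pairs — which slightly
  deflates LD-gated sets if the panel is small.
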