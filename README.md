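# oppeqtl

Detection and characterization of **opposite eQTL effects**: primary
cis-eQTL signals whose direction of effect on the same gene reverses between
tissues.

## The problem

Most genes with a cis-eQTL carry one in several tissues, usually with a
consistent effect direction. The exceptions — a variant that *raises*
expression of a gene in one tissue and *lowers* it in another — mark
tissue-specific regulatory rewiring and are valuable annotations for
interpreting GWAS loci. Calling such reversals from per-tissue summary
statistics requires care: the top (most significant) eQTL SNP of a gene
differs between tissues, so directions may only be compared between top SNPs
that are identical or in strong LD; otherwise one compares independent
primary and secondary signals.

`oppeqtl` implements the full procedure for users of GTEx-style per-tissue
significant variant-gene tables:

1. **Top-SNP extraction** — per gene and tissue, the minimum-p SNP, with
   exact ties broken by byte-wise rsid order ("rs10" < "rs2"), after
   removing indels, multi-allelic SNPs and variants absent from the
   reference haplotype panel.
2. **2×2 analysis tables** — for gene *g* and tissue pair (*x*, *y*), with
   β<sub>ij</sub> the effect of SNP-*i* (top SNP of tissue *i*) in tissue
   *j* and 0 encoding "not significant": eligible iff the SNPs are
   identical or one is significant in both tissues; **opposite** iff
   β<sub>xx</sub>β<sub>xy</sub> ≤ 0 and β<sub>yx</sub>β<sub>yy</sub> ≤ 0;
   crossed with LD (r² > 0.8, strict; 1 for identical SNPs) into groups
   1a/1b/2a/2b. r² comes from a phased reference panel by haplotype
   frequency counting: r² = (p<sub>AB</sub> − p<sub>A</sub>p<sub>B</sub>)² /
   (p<sub>A</sub>(1−p<sub>A</sub>)p<sub>B</sub>(1−p<sub>B</sub>)).
3. **Designations** — genes/SNPs in ≥ 1 group-1a-or-2a table are
   *multi-eQTL* sets; those in ≥ 1 group-1a table are *opp-multi-eQTL*
   sets (opp ⊆ multi ⊆ all).
4. **Tissue statistics** — per-tissue counts/ratios, the tissue-pair
   opposite-fraction matrix with complete-linkage clustering, and 2-d
   p-value deviation densities.
5. **Enrichment** — TSS proximity (sample-kurtosis statistic against a
   sharing-matched resampling null), epigenetic annotations (mean fraction
   across cell lines against a TSS-distance-matched null with resampled 95%
   CI), and GWAS-catalog LD overlap (Fisher exact plus the same resampling
   null), all with strict-bound p reporting (p < 1/n<sub>rep</sub>).
6. **Locus views** — allele-harmonized regional β/p plots for a tissue
   pair (anchor betas made non-negative by joint ref/alt reassignment).
7. **Synthetic cohorts** — a seeded generator with planted ground truth
   (block-diagonal LD panel, planted opposite genes, TSS-decay, annotation
   and GWAS-partner knobs) that emits every input dialect the pipeline
   reads, so the whole analysis is testable offline.

## Worked example

```r
library(oppeqtl)

cfg     <- simConfig(seed = 1)                  # 200 genes x 6 tissues
cohort  <- simulateCohort(cfg)
filtered <- lapply(cohort$tables, filterVariants,
                   panelKeys = variantKeys(cohort$panel))
top <- extractTopEqtl(filtered)
ats <- classifyTissuePairs(top, filtered, cohort$panel)
des <- aggregateDesignations(ats, top)
ats
#> AnalysisTableSet: 616 eligible-candidate tables (r2 threshold 0.80)
#> excluded group_1a group_1b group_2a group_2b
#>        0       43        0      573        0
des
#> DesignationSets
#>   eQTL-Genes: 200  top-eQTL-SNPs: 169
#>   multi-eQTL-Genes: 136  multi-eQTL-SNPs: 121
#>   opp-multi-eQTL-Genes: 27  opp-multi-eQTL-SNPs: 27
```

Of 200 simulated genes, 136 share their top signal between at least one
tissue pair (multi), and 27 reverse direction in at least one pair (opp) —
exactly the 27 genes the generator planted, with no false calls. Enrichment
of the opp class then runs against matched resampling nulls:

```r
ds  <- buildDistanceSamples(des, filtered, top)
tss <- tssEnrichmentPvalue(ds$opp, ds$multi, nRep = 10000, seed = 2)
#> opp TSS kurtosis 8.14 vs adjusted-multi mean 8.41 (p = 0.4261)

gw <- loadGwasCatalog(gwasFile)   # catalog TSV written by the generator
classLdOverlap(oppSnps(des), gw, cohort$panel)
#> GWAS-LD overlap: opp 9/27 (33.3%) vs multi 31/121 (25.6%)
```

At this small cohort size the TSS-kurtosis test is properly conservative
(27 opp pairs), while the GWAS-LD overlap of the opp class sits above the
multi class, as planted. See the methods vignette
(`vignettes/opposite-eqtl-methods.Rmd`) for the model, the matched-null
constructions and all tunable parameters.

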