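## S4 class definitions for the opposite-eQTL pipeline.

#' TissueTable: significant cis-eQTL associations of one tissue
#'
#' One row per significant variant-gene pair of a single tissue, in the
#' summary-statistics dialect of per-tissue "signif_variant_gene_pairs"
#' tables: stable gene id, variant key (chrom_pos_ref_alt_build, 1-based
#' GRCh37), dbSNP rsid, signed slope (beta) of the alt allele on expression,
#' nominal p-value, and the signed base-pair distance of the variant from the
#' gene's TSS.
#'
#' Significance is extensional: a (gene, SNP) pair is significant in a tissue
#' iff it appears in that tissue's table. Betas of exactly 0 are disallowed so
#' that 0 can unambiguously encode "not significant" downstream.
#'
#' @slot tissue single tissue code (e.g. "WHLBLD").
#' @slot organSystem organ-system category label (pass-through metadata).
#' @slot records data.frame with columns gene_id, variant_key, rsid, beta,
#'   pval, tss_distance.
#' @export
setClass("TissueTable", representation(
  tissue = "character",
  organSystem = "character",
  records = "data.frame"
))

setValidity("TissueTable", function(object) {
  r <- object@records
  need <- c("gene_id", "variant_key", "rsid", "beta", "pval", "tss_distance")
  if (!all(need %in% names(r))) {
    return(paste("records must have columns:", paste(setdiff(need, names(r)), collapse = ", ")))
  }
  if (length(object@tissue) != 1L) return("tissue must be a single code")
  if (nrow(r)) {
    if (any(r$pval <= 0)) return("pval must be > 0")
    if (any(r$beta == 0)) return("beta == 0 is reserved for 'not significant'")
    if (any(abs(r$tss_distance) > 1e6)) return("|tss_distance| must be <= 1 Mb (cis window)")
    if (anyDuplicated(paste(r$gene_id, r$variant_key))) {
      return("(gene_id, variant_key) must be unique within a tissue")
    }
    ## keys must parse; non-SNP variants (indels) may be present before
    ## panel filtering and are removed by filterVariants()
    if (anyNA(parseVariantKey(r$variant_key)$pos)) {
      return("variant_key must parse as chrom_pos_ref_alt_build")
    }
  }
  TRUE
})

#' TopEqtlMap: per-gene per-tissue top eQTL SNPs
#'
#' For each gene and tissue with at least one significant record, the single
#' SNP with the smallest nominal p-value (ties broken by plain byte-wise
#' string order of the rsid, so "rs10" < "rs2").
#'
#' @slot entries data.frame with columns gene_id, tissue, rsid, variant_key,
#'   beta, pval, tss_distance; one row per (gene, tissue).
#' @export
setClass("TopEqtlMap", representation(entries = "data.frame"))

setValidity("TopEqtlMap", function(object) {
  e <- object@entries
  need <- c("gene_id", "tissue", "rsid", "variant_key", "beta", "pval", "tss_distance")
  if (!all(need %in% names(e))) {
    return(paste("entries must have columns:", paste(setdiff(need, names(e)), collapse = ", ")))
  }
  if (anyDuplicated(paste(e$gene_id, e$tissue))) {
    return("exactly one top SNP per (gene, tissue)")
  }
  TRUE
})

#' HaplotypePanel: phased biallelic reference haplotypes
#'
#' Binary matrix of phased haplotypes (variants in rows, haplotypes in
#' columns; 0 = ref allele, 1 = alt allele) with variant coordinates and
#' rsids, emulating a 1000-Genomes-style reference panel for LD (r^2)
#' computation.
#'
#' @slot variantKeys character, unique variant keys (chrom_pos_ref_alt_build).
#' @slot rsids character, unique rsids aligned with variantKeys.
#' @slot chrom,pos parsed coordinates aligned with variantKeys.
#' @slot haplotypes integer matrix in \{0,1\}, variants x haplotypes.
#' @slot population population label, e.g. "EUR".
#' @export
setClass("HaplotypePanel", representation(
  variantKeys = "character",
  rsids = "character",
  chrom = "character",
  pos = "integer",
  haplotypes = "matrix",
  population = "character"
))

setValidity("HaplotypePanel", function(object) {
  H <- object@haplotypes
  n <- length(object@variantKeys)
  if (nrow(H) != n) return("haplotype matrix rows must match variantKeys")
  if (ncol(H) < 2L) return("panel needs >= 2 haplotypes")
  if (length(object@rsids) != n || length(object@chrom) != n || length(object@pos) != n) {
    return("rsids/chrom/pos must align with variantKeys")
  }
  if (anyDuplicated(object@variantKeys)) return("variantKeys must be unique")
  if (anyDuplicated(object@rsids)) return("rsids must be unique")
  if (n && !all(H %in% c(0L, 1L))) return("haplotype entries must be 0/1")
  TRUE
})

#' AnalysisTableSet: 2x2 direction/LD analysis tables for gene x tissue-pair
#'
#' One row per (gene, unordered tissue pair) where the gene has a top eQTL
#' SNP in both tissues. beta_ij is the effect of SNP-i (the top SNP of
#' tissue i) in tissue j, with 0 encoding "not significant in that tissue".
#' status partitions rows into excluded (neither cross-significant and SNPs
#' differ) and groups 1a (opposite direction, r^2 > threshold), 1b (opposite,
#' r^2 <= threshold), 2a (same, r^2 > threshold), 2b (same, r^2 <= threshold).
#'
#' @slot tables data.frame with columns gene_id, tissue_x, tissue_y, snp_x,
#'   snp_y, beta_xx, beta_xy, beta_yx, beta_yy, pval_x, pval_y, r2, direction,
#'   status.
#' @slot r2Threshold the LD threshold used for group assignment.
#' @slot nGenes,nTissues cohort dimensions used (for table-count accounting).
#' @export
setClass("AnalysisTableSet", representation(
  tables = "data.frame",
  r2Threshold = "numeric",
  nGenes = "integer",
  nTissues = "integer"
))

setValidity("AnalysisTableSet", function(object) {
  t <- object@tables
  need <- c("gene_id", "tissue_x", "tissue_y", "snp_x", "snp_y",
            "beta_xx", "beta_xy", "beta_yx", "beta_yy",
            "pval_x", "pval_y", "r2", "direction", "status")
  if (!all(need %in% names(t))) {
    return(paste("tables must have columns:", paste(setdiff(need, names(t)), collapse = ", ")))
  }
  okStatus <- c("ineligible", "excluded", "group_1a", "group_1b", "group_2a", "group_2b")
  if (nrow(t) && !all(t$status %in% okStatus)) return("invalid status value")
  if (nrow(t) && any(t$tissue_x == t$tissue_y)) return("tissue_x must differ from tissue_y")
  TRUE
})

#' DesignationSets: nested gene/SNP designations
#'
#' The nested designations produced by aggregating all analysis tables:
#' eQTL-Genes (any significant signal anywhere) with their top-eQTL-SNPs;
#' multi-eQTL-Genes/SNPs (top SNPs identical or in LD, r^2 > threshold, in at
#' least one tissue pair: groups 1a or 2a); opp-multi-eQTL-Genes/SNPs
#' (additionally opposite effect direction: group 1a). The evidence slot keeps
#' every qualifying tissue pair per designated gene.
#'
#' @slot eqtlGenes,topEqtlSnps,multiGenes,multiSnps,oppGenes,oppSnps character sets.
#' @slot evidence data.frame of qualifying tables (gene_id, tissue_x, tissue_y,
#'   snp_x, snp_y, group).
#' @export
setClass("DesignationSets", representation(
  eqtlGenes = "character",
  topEqtlSnps = "character",
  multiGenes = "character",
  multiSnps = "character",
  oppGenes = "character",
  oppSnps = "character",
  evidence = "data.frame"
))

setValidity("DesignationSets", function(object) {
  if (!all(object@oppGenes %in% object@multiGenes)) return("opp genes must be a subset of multi genes")
  if (!all(object@multiGenes %in% object@eqtlGenes)) return("multi genes must be a subset of eQTL genes")
  if (!all(object@oppSnps %in% object@multiSnps)) return("opp SNPs must be a subset of multi SNPs")
  if (!all(object@multiSnps %in% object@topEqtlSnps)) return("multi SNPs must be a subset of top eQTL SNPs")
  TRUE
})

#' OppositeFractionMatrix: per tissue pair, fraction of sign-discordant records
#'
#' Symmetric tissue x tissue matrix; entry (i, j) is the proportion of
#' (gene, SNP) records significant in both tissues whose betas have opposite
#' sign. Diagonal is 0 by convention; pairs with no shared records are NA.
#'
#' @slot tissues ordered tissue codes.
#' @slot fraction symmetric numeric matrix of opposite fractions.
#' @slot nShared symmetric integer matrix of shared-record counts.
#' @export
setClass("OppositeFractionMatrix", representation(
  tissues = "character",
  fraction = "matrix",
  nShared = "matrix"
))

setValidity("OppositeFractionMatrix", function(object) {
  f <- object@fraction
  n <- length(object@tissues)
  if (!all(dim(f) == c(n, n)) || !all(dim(object@nShared) == c(n, n))) {
    return("matrices must be tissues x tissues")
  }
  if (n && !isTRUE(all.equal(f, t(f)))) return("fraction matrix must be symmetric")
  vals <- f[!is.na(f)]
  if (length(vals) && (any(vals < 0) || any(vals > 1))) return("fractions must lie in [0,1]")
  TRUE
})

#' DistanceSample: TSS distances of one SNP class
#'
#' Signed TSS distances (bp) of the unique (gene, SNP) pairs of one SNP class
#' (any-eQTL, top, multi, adjusted-multi, opp), together with each pair's
#' number of sharing tissues (tissues in which the same gene-SNP pair is
#' significant).
#'
#' @slot label class name.
#' @slot pairs data.frame with columns gene_id, rsid, tss_distance, sharing.
#' @export
setClass("DistanceSample", representation(label = "character", pairs = "data.frame"))

setValidity("DistanceSample", function(object) {
  p <- object@pairs
  need <- c("gene_id", "rsid", "tss_distance", "sharing")
  if (!all(need %in% names(p))) {
    return(paste("pairs must have columns:", paste(setdiff(need, names(p)), collapse = ", ")))
  }
  if (nrow(p)) {
    if (any(abs(p$tss_distance) > 1e6)) return("|tss_distance| must be <= 1 Mb")
    if (any(p$sharing < 1)) return("sharing counts must be >= 1")
  }
  TRUE
})

#' AnnotationMatrix: SNP x cell-line x mark epigenetic annotations
#'
#' Boolean presence of each epigenetic mark (H3K4me1, H3K4me3, H3K9ac,
#' H3K27ac, DNase) per SNP and cell line, with an availability mask saying
#' for which (cell, mark) combinations annotation data exist at all.
#'
#' @slot presence logical 3-d array, dim snp x cell x mark (named).
#' @slot availability logical matrix, cell x mark.
#' @export
setClass("AnnotationMatrix", representation(presence = "array", availability = "matrix"))

setValidity("AnnotationMatrix", function(object) {
  d <- dim(object@presence)
  if (length(d) != 3L) return("presence must be a 3-d array (snp x cell x mark)")
  if (!all(dim(object@availability) == d[2:3])) return("availability must be cell x mark")
  for (m in seq_len(d[3])) {
    un <- !object@availability[, m]
    if (any(un) && any(object@presence[, un, m])) {
      return("presence only allowed where (cell, mark) data are available")
    }
  }
  TRUE
})

#' GwasSnpSet: genome-wide-significant GWAS-catalog SNPs
#'
#' Unique trait-associated rsids retained at a strict reported-p threshold
#' (default 5e-8); multi-trait duplicates are collapsed keeping the minimum p.
#'
#' @slot rsids character set of retained rsids.
#' @slot pvalues named numeric, minimum reported p per rsid.
#' @slot threshold the strict "<" threshold applied.
#' @export
setClass("GwasSnpSet", representation(
  rsids = "character", pvalues = "numeric", threshold = "numeric"
))

setValidity("GwasSnpSet", function(object) {
  if (length(object@rsids) != length(object@pvalues)) return("rsids and pvalues must align")
  if (length(object@pvalues) && any(object@pvalues >= object@threshold)) {
    return("all retained p-values must be strictly below the threshold")
  }
  TRUE
})

#' LocusView: allele-harmonized regional association view
#'
#' All tested SNPs within a window of a gene's TSS for a tissue pair, with
#' ref/alt reassigned per SNP so the anchor tissue's betas are all
#' non-negative; the other tissue's betas are re-signed jointly, so sign
#' products (and hence any direction call) are preserved.
#'
#' @slot geneId gene identifier.
#' @slot anchorTissue,otherTissue tissue codes.
#' @slot rows data.frame with columns rsid, pos, beta_anchor, beta_other,
#'   mlog10p_anchor, mlog10p_other, flipped, highlighted; sorted by pos.
#' @export
setClass("LocusView", representation(
  geneId = "character",
  anchorTissue = "character",
  otherTissue = "character",
  rows = "data.frame"
))

setValidity("LocusView", function(object) {
  r <- object@rows
  need <- c("rsid", "pos", "beta_anchor", "beta_other",
            "mlog10p_anchor", "mlog10p_other", "flipped", "highlighted")
  if (!all(need %in% names(r))) {
    return(paste("rows must have columns:", paste(setdiff(need, names(r)), collapse = ", ")))
  }
  ba <- r$beta_anchor[!is.na(r$beta_anchor)]
  if (length(ba) && any(ba < 0)) return("beta_anchor must be >= 0 after reassignment")
  if (nrow(r) > 1 && is.unsorted(r$pos)) return("rows must be sorted by position")
  TRUE
})

#' SimConfig: synthetic multi-tissue eQTL cohort configuration
#'
#' Parameters of the synthetic-data generator: cohort dimensions, the
#' block-diagonal LD structure of the haplotype panel, the planted fraction of
#' opposite-effect genes, effect-size and tissue-sharing models, detection
#' (significance censoring), the TSS-distance model (uniform cis background
#' plus a Laplace peak at the TSS, sharper for planted opposite genes), and
#' annotation/GWAS enrichment knobs. The seed is mandatory; every generator
#' output is a deterministic function of the config.
#'
#' @slot nTissues,nGenes,nHaplotypes,nBlocks,snpsPerBlock cohort dimensions.
#' @slot blockR2Target target within-block r^2 (+/- 0.1).
#' @slot thetaOpp fraction of genes planted with an opposite effect pair.
#' @slot betaMeanlog,betaSdlog log-normal parameters of |beta|.
#' @slot sharingGeomProb geometric parameter of the number of active tissues.
#' @slot censorSlope,censorMid logistic detection-probability parameters on
#'   scaled |beta|; tissueScaleRange range of per-tissue sample-size scales.
#' @slot causalDropRate probability a causal record is censored per tissue.
#' @slot partnerMinAbsR minimum |r| for an LD partner to be emitted.
#' @slot tssPeakScale,tssPeakScaleOpp Laplace scale (bp) of the TSS peak.
#' @slot tssBackground,tssBackgroundOpp uniform-background mixture weight.
#' @slot annotationRate,annotationBoost,availabilityRate,nCells annotation model.
#' @slot gwasRho,gwasBackgroundN,gwasNonsigN GWAS-catalog model.
#' @slot seed master seed (mandatory).
#' @export
setClass("SimConfig", representation(
  nTissues = "integer", nGenes = "integer", nHaplotypes = "integer",
  nBlocks = "integer", snpsPerBlock = "integer", blockR2Target = "numeric",
  thetaOpp = "numeric", betaMeanlog = "numeric", betaSdlog = "numeric",
  sharingGeomProb = "numeric", censorSlope = "numeric", censorMid = "numeric",
  tissueScaleRange = "numeric", causalDropRate = "numeric",
  partnerMinAbsR = "numeric",
  tssPeakScale = "numeric", tssPeakScaleOpp = "numeric",
  tssBackground = "numeric", tssBackgroundOpp = "numeric",
  annotationRate = "numeric", annotationBoost = "numeric",
  availabilityRate = "numeric", nCells = "integer",
  gwasRho = "numeric", gwasBackgroundN = "integer", gwasNonsigN = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  rates <- c(object@thetaOpp, object@sharingGeomProb, object@causalDropRate,
             object@tssBackground, object@tssBackgroundOpp,
             object@annotationRate, object@availabilityRate, object@gwasRho)
  if (any(rates < 0 | rates > 1)) return("all rates must lie in [0,1]")
  if (object@blockR2Target <= 0 || object@blockR2Target > 1) return("blockR2Target must be in (0,1]")
  if (length(object@seed) != 1L || is.na(object@seed)) return("seed is mandatory")
  if (object@nHaplotypes < 2L) return("need >= 2 haplotypes")
  TRUE
})

#' GroundTruth: planted labels of a synthetic cohort
#'
#' @slot genes data.frame: gene_id, label (opposite/concordant/single_tissue),
#'   tissue_a, tissue_b (the planted reversal pair, NA otherwise), causal_rsid,
#'   causal_key, block, tss, n_active.
#' @slot snps data.frame: rsid, annotation_flag, gwas_partner_flag.
#' @export
setClass("GroundTruth", representation(genes = "data.frame", snps = "data.frame"))

setValidity("GroundTruth", function(object) {
  g <- object@genes
  if (nrow(g) && !all(g$label %in% c("opposite", "concordant", "single_tissue"))) {
    return("gene labels must be opposite/concordant/single_tissue")
  }
  TRUE
})
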