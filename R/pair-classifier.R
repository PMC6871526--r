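## Core procedure: 2x2 analysis tables per (gene, tissue pair), direction and
## LD group classification, and aggregation into designation sets.

#' Number of analysis tables for a cohort
#'
#' One 2x2 analysis table exists per gene and unordered tissue pair, i.e.
#' nGenes * choose(nTissues, 2). For 48 tissues there are 1128 tissue pairs.
#'
#' @param nGenes number of eQTL genes.
#' @param nTissues number of tissues.
#' @return the table count (numeric, may exceed integer range).
#' @export
analysisTableCount <- function(nGenes, nTissues) {
  as.numeric(nGenes) * choose(nTissues, 2)
}

## internal: beta of (tissue, gene, variant_key) in the significant tables,
## 0 when the record is absent ("not significant in that tissue").
.betaLookup <- function(tables) {
  pieces <- lapply(tables, function(tt) {
    r <- records(tt)
    data.table::data.table(tissue = tissueCode(tt), gene_id = r$gene_id,
                           variant_key = r$variant_key, beta = r$beta)
  })
  dt <- data.table::rbindlist(pieces)
  data.table::setkey(dt, tissue, gene_id, variant_key)
  dt
}

#' Build one 2x2 analysis table
#'
#' For a gene and an ordered tissue pair (x, y), collects SNP-x / SNP-y (the
#' top eQTL SNPs of the gene in each tissue) and the four effect sizes
#' beta_ij = effect of SNP-i in tissue-j, with 0 encoding "not significant in
#' that tissue". If the gene lacks a significant signal in either tissue the
#' table is ineligible.
#'
#' @param geneId gene identifier.
#' @param tissueX,tissueY tissue codes (must differ).
#' @param top a \linkS4class{TopEqtlMap}.
#' @param tables named list of \linkS4class{TissueTable} (names = tissue codes).
#' @return one-row data.frame with columns gene_id, tissue_x, tissue_y, snp_x,
#'   snp_y, beta_xx, beta_xy, beta_yx, beta_yy, pval_x, pval_y, r2 (NA until
#'   assigned), direction (NA), status ("ineligible" or "pending").
#' @export
buildAnalysisTable <- function(geneId, tissueX, tissueY, top, tables) {
  stopifnot(tissueX != tissueY)
  e <- topEntries(top)
  ex <- e[e$gene_id == geneId & e$tissue == tissueX, , drop = FALSE]
  ey <- e[e$gene_id == geneId & e$tissue == tissueY, , drop = FALSE]
  lookup <- function(tissue, key) {
    if (is.null(tables[[tissue]])) return(0)
    r <- records(tables[[tissue]])
    hit <- r$beta[r$gene_id == geneId & r$variant_key == key]
    if (length(hit)) hit[1L] else 0
  }
  row <- data.frame(
    gene_id = geneId, tissue_x = tissueX, tissue_y = tissueY,
    snp_x = if (nrow(ex)) ex$rsid else NA_character_,
    snp_y = if (nrow(ey)) ey$rsid else NA_character_,
    beta_xx = if (nrow(ex)) ex$beta else 0,
    beta_xy = if (nrow(ex)) lookup(tissueY, ex$variant_key) else 0,
    beta_yx = if (nrow(ey)) lookup(tissueX, ey$variant_key) else 0,
    beta_yy = if (nrow(ey)) ey$beta else 0,
    pval_x = if (nrow(ex)) ex$pval else NA_real_,
    pval_y = if (nrow(ey)) ey$pval else NA_real_,
    r2 = NA_real_, direction = NA_character_,
    status = "pending", stringsAsFactors = FALSE
  )
  if (row$beta_xx == 0 || row$beta_yy == 0) row$status <- "ineligible"
  row
}

#' Eligibility of an analysis table
#'
#' A table (gene significant in both tissues) is eligible for a direction call
#' iff (i) SNP-x and SNP-y are identical, or (ii) at least one of them is
#' significant in both tissues (beta_xy != 0 or beta_yx != 0).
#'
#' @param tables data.frame of analysis-table rows (vectorized).
#' @return logical vector.
#' @export
eligibility <- function(tables) {
  tables$snp_x == tables$snp_y | tables$beta_xy != 0 | tables$beta_yx != 0
}

#' Direction call of an analysis table
#'
#' Opposite iff beta_xx * beta_xy <= 0 AND beta_yx * beta_yy <= 0 (a zero
#' cross-beta satisfies "<= 0"); otherwise same.
#'
#' @param tables data.frame of eligible analysis-table rows (vectorized).
#' @return character vector "opposite"/"same".
#' @export
classifyDirection <- function(tables) {
  opp <- tables$beta_xx * tables$beta_xy <= 0 & tables$beta_yx * tables$beta_yy <= 0
  ifelse(opp, "opposite", "same")
}

#' Group assignment of an eligible analysis table
#'
#' 1a = opposite and r^2 > threshold; 1b = opposite and r^2 <= threshold;
#' 2a = same and r^2 > threshold; 2b = same and r^2 <= threshold. Identical
#' SNPs carry r^2 = 1; an undefined r^2 (monomorphic SNP) counts as not in LD.
#'
#' @param direction "opposite"/"same" vector.
#' @param r2 numeric vector of r^2 (NA = undefined).
#' @param threshold strict r^2 threshold (default 0.8).
#' @return character vector "group_1a"/"group_1b"/"group_2a"/"group_2b".
#' @export
assignGroup <- function(direction, r2, threshold = 0.8) {
  high <- !is.na(r2) & r2 > threshold
  paste0("group_", ifelse(direction == "opposite", "1", "2"), ifelse(high, "a", "b"))
}

#' Classify all (gene, tissue pair) analysis tables of a cohort
#'
#' Builds and classifies the 2x2 analysis table for every gene and unordered
#' tissue pair in which the gene has a top eQTL SNP in both tissues. Tables
#' where the gene lacks a signal in either tissue are ineligible and not
#' materialized (their count is recoverable from
#' \code{\link{analysisTableCount}} minus the emitted rows).
#'
#' @param top a \linkS4class{TopEqtlMap}.
#' @param tables named list of \linkS4class{TissueTable} (names = tissue codes).
#' @param panel a \linkS4class{HaplotypePanel} for r^2 between distinct top SNPs.
#' @param r2Threshold strict LD threshold for group assignment (default 0.8).
#' @return an \linkS4class{AnalysisTableSet}.
#' @export
classifyTissuePairs <- function(top, tables, panel, r2Threshold = 0.8) {
  e <- data.table::as.data.table(topEntries(top))
  tissues <- sort(names(tables))
  lookup <- .betaLookup(tables)
  pairs <- if (length(tissues) >= 2L) utils::combn(tissues, 2L) else
    matrix(character(0), nrow = 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    tx <- pairs[1L, k]; ty <- pairs[2L, k]
    ex <- e[e$tissue == tx, ]
    ey <- e[e$tissue == ty, ]
    both <- merge(ex, ey, by = "gene_id", suffixes = c("_x", "_y"))
    if (!nrow(both)) next
    bxy <- lookup[data.table::data.table(tissue = ty, gene_id = both$gene_id,
                                         variant_key = both$variant_key_x),
                  on = c("tissue", "gene_id", "variant_key")]$beta
    byx <- lookup[data.table::data.table(tissue = tx, gene_id = both$gene_id,
                                         variant_key = both$variant_key_y),
                  on = c("tissue", "gene_id", "variant_key")]$beta
    out[[k]] <- data.frame(
      gene_id = both$gene_id, tissue_x = tx, tissue_y = ty,
      snp_x = both$rsid_x, snp_y = both$rsid_y,
      beta_xx = both$beta_x,
      beta_xy = ifelse(is.na(bxy), 0, bxy),
      beta_yx = ifelse(is.na(byx), 0, byx),
      beta_yy = both$beta_y,
      pval_x = both$pval_x, pval_y = both$pval_y,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(tab)) {
    tab <- data.frame(gene_id = character(), tissue_x = character(),
                      tissue_y = character(), snp_x = character(),
                      snp_y = character(), beta_xx = numeric(),
                      beta_xy = numeric(), beta_yx = numeric(),
                      beta_yy = numeric(), pval_x = numeric(),
                      pval_y = numeric(), r2 = numeric(),
                      direction = character(), status = character())
  } else {
    ## r^2 for distinct top-SNP pairs, vectorized over unique pairs
    tab$r2 <- 1
    distinct <- tab$snp_x != tab$snp_y
    if (any(distinct)) {
      up <- unique(tab[distinct, c("snp_x", "snp_y")])
      i <- .panelIndex(panel, up$snp_x)
      j <- .panelIndex(panel, up$snp_y)
      H <- panel@haplotypes
      pA <- rowMeans(H[i, , drop = FALSE])
      pB <- rowMeans(H[j, , drop = FALSE])
      pAB <- rowMeans(H[i, , drop = FALSE] * H[j, , drop = FALSE])
      r2 <- (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
      r2[pA <= 0 | pA >= 1 | pB <= 0 | pB >= 1] <- NA_real_
      up$r2 <- r2
      m <- match(paste(tab$snp_x, tab$snp_y), paste(up$snp_x, up$snp_y))
      tab$r2[distinct] <- up$r2[m[distinct]]
    }
    elig <- eligibility(tab)
    tab$direction <- NA_character_
    tab$direction[elig] <- classifyDirection(tab[elig, , drop = FALSE])
    tab$status <- "excluded"
    tab$status[elig] <- assignGroup(tab$direction[elig], tab$r2[elig], r2Threshold)
  }
  methods::new("AnalysisTableSet", tables = tab, r2Threshold = r2Threshold,
               nGenes = length(unique(e$gene_id)), nTissues = length(tissues))
}

#' Aggregate designation sets from classified analysis tables
#'
#' multi-eQTL-Genes/SNPs are the genes and top SNPs appearing in at least one
#' group-1a or group-2a table (top SNPs identical or in LD above the
#' threshold); opp-multi-eQTL-Genes/SNPs those in at least one group-1a table
#' (additionally opposite direction). Both snp_x and snp_y of a qualifying
#' table enter the SNP sets. Every qualifying tissue pair is kept as evidence.
#'
#' @param ats an \linkS4class{AnalysisTableSet}.
#' @param top the \linkS4class{TopEqtlMap} of the cohort (defines the eQTL-Gene
#'   and top-eQTL-SNP universes).
#' @return a \linkS4class{DesignationSets}.
#' @export
aggregateDesignations <- function(ats, top) {
  t <- analysisTables(ats)
  e <- topEntries(top)
  qual <- t[t$status %in% c("group_1a", "group_2a"), , drop = FALSE]
  opp <- qual[qual$status == "group_1a", , drop = FALSE]
  evidence <- data.frame(gene_id = qual$gene_id, tissue_x = qual$tissue_x,
                         tissue_y = qual$tissue_y, snp_x = qual$snp_x,
                         snp_y = qual$snp_y,
                         group = sub("group_", "", qual$status),
                         stringsAsFactors = FALSE)
  methods::new("DesignationSets",
               eqtlGenes = sort(unique(e$gene_id)),
               topEqtlSnps = sort(unique(e$rsid)),
               multiGenes = sort(unique(qual$gene_id)),
               multiSnps = sort(unique(c(qual$snp_x, qual$snp_y))),
               oppGenes = sort(unique(opp$gene_id)),
               oppSnps = sort(unique(c(opp$snp_x, opp$snp_y))),
               evidence = evidence)
}

#' Per-gene/SNP pair counts of designated sets
#'
#' The pair counts reported alongside the designations: the number of unique
#' (gene, SNP) pairs supporting the multi and opp designations.
#'
#' @param designations a \linkS4class{DesignationSets}.
#' @return named list with multiPairs and oppPairs counts.
#' @export
designationPairCounts <- function(designations) {
  ev <- designationEvidence(designations)
  pairKey <- function(d) unique(c(paste(d$gene_id, d$snp_x), paste(d$gene_id, d$snp_y)))
  list(multiPairs = length(pairKey(ev)),
       oppPairs = length(pairKey(ev[ev$group == "1a", , drop = FALSE])))
}
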