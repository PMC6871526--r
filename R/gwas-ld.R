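## LD overlap of SNP classes with genome-wide-significant GWAS-catalog SNPs.

#' Load genome-wide-significant SNPs from a GWAS-catalog TSV
#'
#' Reads the catalog dialect (header row, columns \code{SNPS} with the rsid
#' and \code{P-VALUE} with the reported association p) and retains rsids with
#' p strictly below the threshold. Multi-trait duplicates are collapsed to
#' one entry keeping the minimum p; rows with malformed p-values are skipped
#' and counted.
#'
#' @param path TSV path.
#' @param pThreshold strict threshold (default 5e-8).
#' @return a \linkS4class{GwasSnpSet}; attribute \code{"skipped"} counts
#'   malformed rows.
#' @export
loadGwasCatalog <- function(path, pThreshold = 5e-8) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("SNPS", "P-VALUE")
  if (!all(need %in% names(d))) {
    stop("missing mandatory column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  p <- suppressWarnings(as.numeric(d[["P-VALUE"]]))
  bad <- is.na(p) | !nzchar(d$SNPS)
  nSkipped <- sum(bad)
  if (nSkipped) message(nSkipped, " malformed row(s) skipped in GWAS catalog")
  d <- d[!bad, , drop = FALSE]; p <- p[!bad]
  keep <- p < pThreshold
  d <- d[keep, , drop = FALSE]; p <- p[keep]
  minP <- tapply(p, d$SNPS, min)
  rsids <- sort(names(minP))
  out <- methods::new("GwasSnpSet", rsids = rsids,
                      pvalues = stats::setNames(as.numeric(minP[rsids]), rsids),
                      threshold = pThreshold)
  attr(out, "skipped") <- nSkipped
  out
}

#' LD overlap of a SNP class with the GWAS-SNP set
#'
#' Counts the SNPs of the class whose r^2 with at least one GWAS-SNP is
#' strictly above the threshold (membership in the GWAS set itself counts via
#' self r^2 = 1) and returns the count and proportion of the class.
#'
#' @param snps character vector of class rsids.
#' @param gwas a \linkS4class{GwasSnpSet}.
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param threshold strict r^2 threshold (default 0.8).
#' @return list with count, proportion, hits (named logical) and skipped.
#' @export
classLdOverlap <- function(snps, gwas, panel, threshold = 0.8) {
  res <- ldHitsAgainstSet(unique(snps), gwasRsids(gwas), panel, threshold)
  list(count = res$nHits, proportion = res$proportion,
       hits = res$hits, skipped = res$skipped)
}

#' Fisher's exact enrichment test between two hit proportions
#'
#' Two-sided Fisher's exact test of the 2x2 table
#' [[hitsA, nA - hitsA], [hitsB, nB - hitsB]]; the odds ratio is the
#' conditional maximum-likelihood estimate reported by
#' \code{\link[stats]{fisher.test}}. A table with a zero margin carries no
#' information: p = 1 and the odds ratio is undefined (NA).
#'
#' @param hitsA,nA hits and total of class A.
#' @param hitsB,nB hits and total of class B.
#' @return list with oddsRatio, pvalue, method.
#' @export
fisherEnrichment <- function(hitsA, nA, hitsB, nB) {
  stopifnot(hitsA >= 0, hitsB >= 0, hitsA <= nA, hitsB <= nB)
  m <- matrix(c(hitsA, nA - hitsA, hitsB, nB - hitsB), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(oddsRatio = NA_real_, pvalue = 1, method = "degenerate margin"))
  }
  ft <- stats::fisher.test(m, alternative = "two.sided")
  list(oddsRatio = unname(ft$estimate), pvalue = ft$p.value,
       method = "two-sided Fisher exact; conditional-MLE odds ratio")
}

#' Resampling enrichment of GWAS-LD overlap, opp vs adjusted multi
#'
#' Observed statistic: the GWAS-LD overlap proportion of the opp-multi-eQTL
#' SNPs. Null: per replicate a fresh TSS-distance-window-matched subsample of
#' the multi pairs is drawn and its overlap proportion computed (per-SNP hit
#' status is precomputed once, since it depends only on the SNP). Returns the
#' empirical 95% CI of the replicate proportions and the one-sided exceedance
#' p with strict-bound reporting.
#'
#' @param opp,multi \linkS4class{DistanceSample} objects (pairs carry rsids).
#' @param gwas a \linkS4class{GwasSnpSet}.
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param nRep number of replicates (default 10000).
#' @param seed master seed.
#' @param threshold strict r^2 threshold (default 0.8).
#' @param windowBp,rangeBp TSS-window matching grid (defaults 1000, 1e6).
#' @return list: observed, ci, pvalue, bound, pLabel, nRep, replicates.
#' @export
resamplingEnrichment <- function(opp, multi, gwas, panel, nRep = 10000, seed = 1L,
                                 threshold = 0.8, windowBp = 1000, rangeBp = 1e6) {
  oppOverlap <- classLdOverlap(unique(samplePairs(opp)$rsid), gwas, panel, threshold)
  observed <- oppOverlap$proportion
  mp <- samplePairs(multi)
  multiSnps <- unique(mp$rsid)
  hitFlag <- ldHitsAgainstSet(multiSnps, gwasRsids(gwas), panel, threshold)$hits
  strata <- split(seq_len(nrow(mp)), .tssWindow(mp$tss_distance, windowBp, rangeBp))
  need <- as.list(table(.tssWindow(distances(opp), windowBp, rangeBp)))
  reps <- vapply(seq_len(nRep), function(i) {
    res <- withSeed(subSeed(seed, i), .matchedSample(strata, need))
    snps <- unique(mp$rsid[res$idx])
    if (!length(snps)) return(NA_real_)
    mean(hitFlag[snps])
  }, 0)
  reps <- reps[!is.na(reps)]
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  c(list(observed = observed, ci = ci),
    exceedanceP(reps, observed), list(replicates = reps))
}
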