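## TSS-distance-window-matched subsampling and epigenetic annotation
## enrichment of opp vs adjusted multi SNP sets.

.EPI_MARKS <- c("H3K4me1", "H3K4me3", "H3K9ac", "H3K27ac", "DNase")

## internal: half-open 1-kbp window index of a signed TSS distance, clamped
## into the grid [-range/window, range/window - 1].
.tssWindow <- function(tss, windowBp = 1000, rangeBp = 1e6) {
  kMax <- rangeBp / windowBp
  pmax(pmin(floor(tss / windowBp), kMax - 1), -kMax)
}

#' TSS-distance-window-matched subsample of the multi pairs
#'
#' Builds the TSS-distance-adjusted multi set: the signed TSS-distance axis is
#' cut into half-open 1-kbp windows [k*1000, (k+1)*1000) spanning the cis
#' range; per window, as many multi pairs are drawn (without replacement) as
#' there are opp pairs in that window, capped at availability with the
#' deficit recorded in the \code{"deficit"} attribute.
#'
#' @param multi,opp \linkS4class{DistanceSample} objects.
#' @param windowBp window width in bp (default 1000).
#' @param rangeBp half-width of the distance range (default 1e6).
#' @param seed integer seed; deterministic given the seed.
#' @return a \linkS4class{DistanceSample} labelled "multi_tss_adjusted".
#' @export
tssWindowMatchedSubsample <- function(multi, opp, windowBp = 1000, rangeBp = 1e6, seed = 1L) {
  mp <- samplePairs(multi)
  strata <- split(seq_len(nrow(mp)), .tssWindow(mp$tss_distance, windowBp, rangeBp))
  need <- as.list(table(.tssWindow(distances(opp), windowBp, rangeBp)))
  res <- withSeed(seed, .matchedSample(strata, need))
  out <- distanceSample("multi_tss_adjusted", mp[res$idx, , drop = FALSE])
  attr(out, "deficit") <- res$deficit
  out
}

#' Annotation fraction of a SNP set in one cell line
#'
#' Fraction of the SNPs carrying the epigenetic mark in the given cell line,
#' among the SNPs resolvable in the annotation matrix (unresolvable SNPs are
#' excluded from numerator and denominator; their count is recorded in the
#' \code{"unresolved"} attribute). Requesting a (cell, mark) combination for
#' which no annotation data exist is an error.
#'
#' @param snps character vector of rsids.
#' @param matrix an \linkS4class{AnnotationMatrix}.
#' @param mark one of H3K4me1, H3K4me3, H3K9ac, H3K27ac, DNase.
#' @param cell cell-line identifier.
#' @return fraction in [0, 1] (NA when no SNP resolves).
#' @export
annotationFraction <- function(snps, matrix, mark, cell) {
  av <- matrix@availability
  if (!cell %in% rownames(av) || !mark %in% colnames(av)) {
    stop("unknown cell line or mark: ", cell, " / ", mark)
  }
  if (!av[cell, mark]) stop("no annotation data available for (", cell, ", ", mark, ")")
  snps <- unique(snps)
  res <- snps[snps %in% dimnames(matrix@presence)[[1L]]]
  out <- if (length(res)) mean(matrix@presence[res, cell, mark]) else NA_real_
  attr(out, "unresolved") <- length(snps) - length(res)
  out
}

#' Mean annotation fraction across available cell lines
#'
#' The surrogate enrichment statistic: the mean, over the cell lines with
#' data for the mark, of the per-cell annotation fraction of the SNP set.
#'
#' @inheritParams annotationFraction
#' @return mean fraction (NA when no SNP resolves).
#' @export
meanAnnotationFraction <- function(snps, matrix, mark) {
  cells <- rownames(matrix@availability)[matrix@availability[, mark]]
  if (!length(cells)) stop("no cell line has data for mark ", mark)
  fr <- vapply(cells, function(c) as.numeric(annotationFraction(snps, matrix, mark, c)), 0)
  mean(fr)
}

## internal: per-SNP mean presence over available cells for a mark; replicate
## means of SNP sets reduce to means of this score.
.snpMarkScore <- function(matrix, mark) {
  cells <- matrix@availability[, mark]
  if (!any(cells)) stop("no cell line has data for mark ", mark)
  rowMeans(matrix@presence[, cells, mark, drop = FALSE])
}

#' Annotation enrichment of opp vs TSS-distance-adjusted multi SNPs
#'
#' Observed statistic: the mean annotation fraction (across available cell
#' lines) of the opp-multi-eQTL SNPs for one mark. Null: per replicate the
#' TSS-distance-adjusted multi set is regenerated by window-matched
#' subsampling and its mean fraction computed. The 95% CI is the empirical
#' 2.5/97.5 percentile of the replicate means; the one-sided p-value is the
#' fraction of replicates at least as large as the observed value, with the
#' strict bound p < 1/nRep when none reaches it.
#'
#' @param opp,multi \linkS4class{DistanceSample} objects (pairs carry rsids).
#' @param matrix an \linkS4class{AnnotationMatrix}.
#' @param mark annotation mark.
#' @param nRep number of replicates (default 10000).
#' @param seed master seed.
#' @param windowBp,rangeBp TSS-window matching grid (defaults 1000, 1e6).
#' @return list: mark, observed, ci (length 2), pvalue, bound, pLabel, nRep,
#'   replicates.
#' @export
enrichmentWithCi <- function(opp, multi, matrix, mark, nRep = 10000, seed = 1L,
                             windowBp = 1000, rangeBp = 1e6) {
  score <- .snpMarkScore(matrix, mark)
  observed <- meanAnnotationFraction(unique(samplePairs(opp)$rsid), matrix, mark)
  mp <- samplePairs(multi)
  strata <- split(seq_len(nrow(mp)), .tssWindow(mp$tss_distance, windowBp, rangeBp))
  need <- as.list(table(.tssWindow(distances(opp), windowBp, rangeBp)))
  reps <- vapply(seq_len(nRep), function(i) {
    res <- withSeed(subSeed(seed, i), .matchedSample(strata, need))
    snps <- unique(mp$rsid[res$idx])
    snps <- snps[snps %in% names(score)]
    if (!length(snps)) return(NA_real_)
    mean(score[snps])
  }, 0)
  reps <- reps[!is.na(reps)]
  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  c(list(mark = mark, observed = observed, ci = ci),
    exceedanceP(reps, observed), list(replicates = reps))
}

#' Write an annotation matrix in the long TSV dialect
#'
#' One row per (rsid, cell, mark) combination for which data are available,
#' with a 0/1 presence flag; availability is implied by which (cell, mark)
#' combinations appear.
#'
#' @param matrix an \linkS4class{AnnotationMatrix}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeAnnotationMatrix <- function(matrix, path) {
  d <- dimnames(matrix@presence)
  rows <- list()
  for (m in d[[3L]]) {
    for (c in d[[2L]]) {
      if (!matrix@availability[c, m]) next
      rows[[paste(m, c)]] <- data.frame(rsid = d[[1L]], cell = c, mark = m,
                                        present = as.integer(matrix@presence[, c, m]))
    }
  }
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an annotation matrix from the long TSV dialect
#'
#' @param path TSV path written by \code{\link{writeAnnotationMatrix}}.
#' @return an \linkS4class{AnnotationMatrix}.
#' @export
readAnnotationMatrix <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("rsid", "cell", "mark", "present")
  if (!all(need %in% names(d))) {
    stop("missing column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  snps <- sort(unique(d$rsid)); cells <- sort(unique(d$cell)); marks <- sort(unique(d$mark))
  pres <- array(FALSE, dim = c(length(snps), length(cells), length(marks)),
                dimnames = list(snps, cells, marks))
  avail <- matrix(FALSE, length(cells), length(marks), dimnames = list(cells, marks))
  avail[cbind(match(d$cell, cells), match(d$mark, marks))] <- TRUE
  pres[cbind(match(d$rsid, snps), match(d$cell, cells), match(d$mark, marks))] <-
    d$present > 0
  methods::new("AnnotationMatrix", presence = pres, availability = avail)
}
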