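## Pairwise r^2 from a phased reference haplotype panel, and LD-set queries.

## internal: r^2 between two 0/1 haplotype vectors from frequency counts.
## Returns NA_real_ when either SNP is monomorphic in the panel.
.r2FromVectors <- function(a, b) {
  pA <- mean(a); pB <- mean(b)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  pAB <- mean(a * b)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

.panelIndex <- function(panel, rsid) {
  i <- match(rsid, panel@rsids)
  if (anyNA(i)) stop("SNP(s) absent from panel: ", paste(rsid[is.na(i)], collapse = ", "))
  i
}

#' Pairwise r^2 between two SNPs from phased haplotypes
#'
#' Computes the squared LD correlation from haplotype frequencies over the
#' panel: with alt-allele frequencies pA and pB and haplotype frequency pAB,
#' r^2 = (pAB - pA pB)^2 / (pA (1 - pA) pB (1 - pB)). This equals the squared
#' Pearson correlation of the two 0/1 haplotype vectors. If the two rsids are
#' identical r^2 is exactly 1; if either SNP is monomorphic in the panel the
#' result is undefined (NA), which every caller treats as "not in LD".
#'
#' @param snpA,snpB rsids, both present in the panel.
#' @param panel a \linkS4class{HaplotypePanel}.
#' @return r^2 in [0, 1], or NA when undefined.
#' @export
ldR2 <- function(snpA, snpB, panel) {
  if (identical(snpA, snpB)) return(1)
  i <- .panelIndex(panel, c(snpA, snpB))
  H <- panel@haplotypes
  .r2FromVectors(H[i[1L], ], H[i[2L], ])
}

#' LD-threshold predicate
#'
#' TRUE iff r^2 is defined and strictly greater than the threshold
#' (r^2 exactly equal to the threshold is not "in LD"); an undefined
#' (monomorphic) r^2 yields FALSE.
#'
#' @inheritParams ldR2
#' @param threshold strict r^2 threshold (default 0.8).
#' @return logical scalar.
#' @export
inLd <- function(snpA, snpB, panel, threshold = 0.8) {
  r2 <- ldR2(snpA, snpB, panel)
  !is.na(r2) && r2 > threshold
}

#' LD hits of a query set against a target set
#'
#' A query SNP is a hit iff it is itself a member of the target set (self
#' r^2 = 1) or some target within the search window has r^2 strictly above
#' the threshold. Queries or targets absent from the panel cannot form
#' computed LD pairs and are counted as skipped (such queries can still hit
#' via exact identity with a target).
#'
#' @param queries,targets character vectors of rsids.
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param threshold strict r^2 threshold (default 0.8).
#' @param windowBp only target SNPs within this distance of a query on the
#'   same chromosome are scanned (default 1 Mb, the cis bound).
#' @return list with \code{hits} (named logical per query), \code{nHits},
#'   \code{proportion} (= nHits / length(queries)), and \code{skipped} (number
#'   of query/target rsids unresolvable in the panel).
#' @export
ldHitsAgainstSet <- function(queries, targets, panel, threshold = 0.8, windowBp = 1e6) {
  queries <- unique(queries)
  targets <- unique(targets)
  hits <- stats::setNames(queries %in% targets, queries)
  qi <- match(queries, panel@rsids)
  ti <- match(targets, panel@rsids)
  nSkipped <- sum(is.na(qi)) + sum(is.na(ti))
  if (nSkipped > 0L) {
    warning(nSkipped, " rsid(s) not resolvable in the panel; ",
            "identity matches only for those")
  }
  tIdx <- ti[!is.na(ti)]
  if (length(tIdx)) {
    H <- panel@haplotypes
    tChrom <- panel@chrom[tIdx]
    tPos <- panel@pos[tIdx]
    for (k in seq_along(queries)) {
      if (hits[k] || is.na(qi[k])) next
      cand <- tIdx[tChrom == panel@chrom[qi[k]] & abs(tPos - panel@pos[qi[k]]) <= windowBp]
      if (!length(cand)) next
      a <- H[qi[k], ]
      for (j in cand) {
        r2 <- .r2FromVectors(a, H[j, ])
        if (!is.na(r2) && r2 > threshold) { hits[k] <- TRUE; break }
      }
    }
  }
  list(hits = hits, nHits = sum(hits),
       proportion = if (length(queries)) sum(hits) / length(queries) else NA_real_,
       skipped = nSkipped)
}

#' Read a phased biallelic haplotype panel from VCF
#'
#' Parses a VCF with phased GT fields (e.g. \code{0|1}) into a
#' \linkS4class{HaplotypePanel}. Records that are not biallelic SNPs are
#' dropped with a message. The rsid is taken from the ID column.
#'
#' @param path VCF path (optionally gzipped).
#' @param population population label to attach (default "EUR").
#' @return a \linkS4class{HaplotypePanel}.
#' @export
readHaplotypePanel <- function(path, population = "EUR") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(keep)) message(sum(!keep), " non-biallelic-SNP record(s) dropped from panel")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  nVar <- nrow(gt)
  split2 <- function(col) {
    m <- do.call(rbind, strsplit(col, "[|/]"))
    matrix(as.integer(m), nrow = length(col))
  }
  hapList <- lapply(seq_len(ncol(gt)), function(j) split2(gt[, j]))
  H <- do.call(cbind, hapList)
  key <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"], "b37", sep = "_")
  methods::new("HaplotypePanel",
               variantKeys = key,
               rsids = as.character(fix[, "ID"]),
               chrom = as.character(fix[, "CHROM"]),
               pos = as.integer(fix[, "POS"]),
               haplotypes = H,
               population = population)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits a minimal VCFv4.2 with phased diploid GT columns (haplotypes paired
#' in order); round-trips through \code{\link{readHaplotypePanel}}. An odd
#' trailing haplotype is not representable and raises an error.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
writePanelVcf <- function(panel, path) {
  H <- panel@haplotypes
  if (ncol(H) %% 2L != 0L) stop("need an even number of haplotypes to emit diploid GT")
  nInd <- ncol(H) / 2L
  p <- parseVariantKey(panel@variantKeys)
  gtCols <- vapply(seq_len(nInd), function(i) {
    paste(H[, 2L * i - 1L], H[, 2L * i], sep = "|")
  }, character(nrow(H)))
  if (is.null(dim(gtCols))) gtCols <- matrix(gtCols, nrow = nrow(H))
  body <- cbind(p$chrom, p$pos, panel@rsids, p$ref, p$alt, ".", "PASS", ".", "GT", gtCols)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            sprintf("IND%04d", seq_len(nInd))), collapse = "\t"),
    apply(body, 1L, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
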