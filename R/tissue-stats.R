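## Per-tissue designation counts, the tissue-pair opposite-fraction matrix,
## clustering of tissues, and p-value deviation densities.

#' TissueSummary: per-tissue designation counts and ratios
#'
#' @slot summary data.frame: tissue, n_eqtl_genes, n_multi_genes, n_opp_genes,
#'   multi_over_eqtl, opp_over_eqtl, opp_over_multi.
#' @slot cv named numeric, cohort-level coefficient of variation
#'   (sample sd / mean over tissues) of each count and ratio column.
#' @slot ratioCor named numeric, Pearson correlations between ratio columns.
#' @export
setClass("TissueSummary", representation(
  summary = "data.frame", cv = "numeric", ratioCor = "numeric"
))

setMethod("show", "TissueSummary", function(object) {
  cat("TissueSummary over", nrow(object@summary), "tissues\n")
  cat("  CV:", paste(sprintf("%s=%.3f", names(object@cv), object@cv), collapse = ", "), "\n")
  cat("  ratio correlations:",
      paste(sprintf("%s=%.3f", names(object@ratioCor), object@ratioCor), collapse = ", "), "\n")
})

#' Per-tissue counts and proportions of designated genes
#'
#' For each tissue: the number of eQTL genes (genes with any significant
#' signal in that tissue), of multi-eQTL genes and of opp-multi-eQTL genes. A
#' gene counts for a tissue's multi/opp tally iff that tissue participates in
#' at least one qualifying tissue pair for the gene. Ratios multi/eqtl,
#' opp/eqtl and opp/multi are reported per tissue, together with the
#' cohort-level CV of each column and the Pearson correlation between ratio
#' columns. Tissues with zero eQTL genes get NA ratios.
#'
#' @param designations a \linkS4class{DesignationSets} (with evidence).
#' @param top the cohort's \linkS4class{TopEqtlMap}.
#' @return a \linkS4class{TissueSummary}.
#' @export
perTissueCounts <- function(designations, top) {
  e <- topEntries(top)
  ev <- designationEvidence(designations)
  tissues <- sort(unique(e$tissue))
  nEqtl <- vapply(tissues, function(t) length(unique(e$gene_id[e$tissue == t])), 0L)
  countFor <- function(d) {
    vapply(tissues, function(t) {
      sel <- d$tissue_x == t | d$tissue_y == t
      length(unique(d$gene_id[sel]))
    }, 0L)
  }
  nMulti <- countFor(ev)
  nOpp <- countFor(ev[ev$group == "1a", , drop = FALSE])
  safeDiv <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  s <- data.frame(tissue = tissues, n_eqtl_genes = nEqtl,
                  n_multi_genes = nMulti, n_opp_genes = nOpp,
                  multi_over_eqtl = safeDiv(nMulti, nEqtl),
                  opp_over_eqtl = safeDiv(nOpp, nEqtl),
                  opp_over_multi = safeDiv(nOpp, nMulti),
                  stringsAsFactors = FALSE, row.names = NULL)
  cvOf <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x)
  }
  cv <- vapply(s[, -1L, drop = FALSE], cvOf, 0)
  corSafe <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }
  ratioCor <- c(
    multi_vs_opp_over_eqtl = corSafe(s$multi_over_eqtl, s$opp_over_eqtl),
    multi_vs_opp_over_multi = corSafe(s$multi_over_eqtl, s$opp_over_multi)
  )
  methods::new("TissueSummary", summary = s, cv = cv, ratioCor = ratioCor)
}

#' Opposite-fraction matrix over tissue pairs
#'
#' For every unordered tissue pair, compares the betas of all (gene, SNP)
#' records significant in BOTH tissues (not only top SNPs) and reports the
#' proportion with opposite sign (beta_i * beta_j < 0; both betas are nonzero
#' by construction). Pairs with no shared records are NA (flagged); the
#' diagonal is 0 by convention.
#'
#' @param tables named list of (filtered) \linkS4class{TissueTable}.
#' @return an \linkS4class{OppositeFractionMatrix}.
#' @export
oppositeFractionMatrix <- function(tables) {
  tissues <- sort(names(tables))
  n <- length(tissues)
  dts <- lapply(tables[tissues], function(tt) {
    r <- records(tt)
    dt <- data.table::data.table(gene_id = r$gene_id, variant_key = r$variant_key,
                                 beta = r$beta)
    data.table::setkey(dt, gene_id, variant_key)
    dt
  })
  frac <- matrix(NA_real_, n, n, dimnames = list(tissues, tissues))
  shared <- matrix(0L, n, n, dimnames = list(tissues, tissues))
  diag(frac) <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      m <- merge(dts[[i]], dts[[j]], by = c("gene_id", "variant_key"))
      shared[i, j] <- shared[j, i] <- nrow(m)
      if (nrow(m)) {
        f <- mean(m$beta.x * m$beta.y < 0)
        frac[i, j] <- frac[j, i] <- f
      }
    }
  }
  methods::new("OppositeFractionMatrix", tissues = tissues,
               fraction = frac, nShared = shared)
}

#' Hierarchical clustering of tissues by opposite-eQTL fractions
#'
#' Agglomerative hierarchical clustering (complete linkage) of the tissues
#' using Euclidean distance between rows of the opposite-fraction matrix.
#' Undefined entries are imputed with the column mean (with a warning) before
#' clustering; clustering is deterministic for identical input.
#'
#' @param ofm an \linkS4class{OppositeFractionMatrix}.
#' @param method linkage method passed to \code{\link[stats]{hclust}}
#'   (default "complete").
#' @return an object of class \code{hclust}.
#' @export
clusterTissues <- function(ofm, method = "complete") {
  f <- ofm@fraction
  if (nrow(f) < 2L) stop("clustering requires >= 2 tissues")
  if (anyNA(f)) {
    warning("undefined opposite fractions imputed with column means")
    for (j in seq_len(ncol(f))) {
      nas <- is.na(f[, j])
      if (any(nas)) f[nas, j] <- mean(f[, j], na.rm = TRUE)
    }
  }
  stats::hclust(stats::dist(f, method = "euclidean"), method = method)
}

#' Export a tissue dendrogram as newick text
#'
#' @param hc an \code{hclust} object from \code{\link{clusterTissues}}.
#' @param path optional output path; when NULL the newick string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' 2-d densities of top-SNP p-value deviation within tissue pairs
#'
#' For every qualifying (group 1a or 2a) analysis table, the two top-SNP
#' p-values of its tissue pair are ordered: p-value_1 is the lower one,
#' p-value_2 the higher one, and mapped to (-log10 p-value_1, -log10
#' p-value_2); since p-value_1 <= p-value_2 the first coordinate always
#' reaches at least the second. Normalized 2-d histograms on a shared fixed
#' grid (0.25-unit bins on [0, 30], larger values clipped into the last bin)
#' are returned for the multi set (1a and 2a) and the opp set (1a), together
#' with their difference (opp - multi), which sums to 0.
#'
#' @param ats an \linkS4class{AnalysisTableSet}.
#' @param binWidth histogram bin width on the -log10 p scale (default 0.25).
#' @param maxLog upper clip of the grid (default 30).
#' @return list with matrices \code{multi}, \code{opp}, \code{difference}
#'   (rows = -log10 p-value_1 bins, columns = -log10 p-value_2 bins) and the
#'   bin \code{breaks}.
#' @export
pvalueDeviationDensity <- function(ats, binWidth = 0.25, maxLog = 30) {
  t <- analysisTables(ats)
  breaks <- seq(0, maxLog, by = binWidth)
  nb <- length(breaks) - 1L
  hist2 <- function(rows) {
    h <- matrix(0, nb, nb)
    if (!nrow(rows)) return(h)
    p1 <- pmin(rows$pval_x, rows$pval_y)
    p2 <- pmax(rows$pval_x, rows$pval_y)
    x <- pmin(-log10(p1), maxLog - 1e-9)
    y <- pmin(-log10(p2), maxLog - 1e-9)
    ix <- pmin(floor(x / binWidth) + 1L, nb)
    iy <- pmin(floor(y / binWidth) + 1L, nb)
    for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
    h / sum(h)
  }
  multi <- hist2(t[t$status %in% c("group_1a", "group_2a"), , drop = FALSE])
  opp <- hist2(t[t$status == "group_1a", , drop = FALSE])
  list(multi = multi, opp = opp, difference = opp - multi, breaks = breaks)
}
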