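## Regional (Fig.-5-style) locus views: allele-harmonized beta/p distributions
## of all tested SNPs around a gene's TSS for a tissue pair.

## internal: coerce an all-associations input (TissueTable or data.frame in
## the records dialect) to a records data.frame.
.assocRecords <- function(x) {
  if (methods::is(x, "TissueTable")) return(records(x))
  need <- c("gene_id", "variant_key", "rsid", "beta", "pval", "tss_distance")
  if (!all(need %in% names(x))) {
    stop("all-associations table must have columns: ", paste(need, collapse = ", "))
  }
  x
}

#' Build an allele-harmonized locus view for a tissue pair
#'
#' Collects all tested SNPs (significant or not) within the window of the
#' gene's TSS in both tissues. For every SNP whose beta in the anchor tissue
#' is negative, ref/alt are reassigned: both tissues' betas of that SNP are
#' negated together, so after harmonization all anchor betas are
#' non-negative and sign products between tissues are unchanged. SNPs
#' untested in the anchor tissue are left unflipped. Rows are sorted by
#' chromosomal position; designated opp-multi-eQTL SNPs are flagged.
#'
#' @param geneId gene identifier.
#' @param anchorTissue,otherTissue tissue codes.
#' @param allAssoc named list (by tissue code) of all-tested association
#'   tables: \linkS4class{TissueTable} objects or data.frames with the record
#'   columns gene_id, variant_key, rsid, beta, pval, tss_distance.
#' @param oppSnps rsids to highlight (e.g. \code{oppSnps(designations)}).
#' @param windowBp TSS window half-width (default 1 Mb).
#' @return a \linkS4class{LocusView}.
#' @export
buildLocusView <- function(geneId, anchorTissue, otherTissue, allAssoc,
                           oppSnps = character(), windowBp = 1e6) {
  getRows <- function(tissue) {
    r <- .assocRecords(allAssoc[[tissue]])
    r <- r[r$gene_id == geneId & abs(r$tss_distance) <= windowBp, , drop = FALSE]
    if (!nrow(r)) stop("gene ", geneId, " absent from the ", tissue, " associations")
    r
  }
  a <- getRows(anchorTissue)
  b <- getRows(otherTissue)
  keys <- union(a$variant_key, b$variant_key)
  ia <- match(keys, a$variant_key)
  ib <- match(keys, b$variant_key)
  pos <- parseVariantKey(keys)$pos
  rows <- data.frame(
    rsid = ifelse(is.na(ia), b$rsid[ib], a$rsid[ia]),
    pos = pos,
    beta_anchor = a$beta[ia],
    beta_other = b$beta[ib],
    mlog10p_anchor = -log10(a$pval[ia]),
    mlog10p_other = -log10(b$pval[ib]),
    stringsAsFactors = FALSE
  )
  rows$flipped <- !is.na(rows$beta_anchor) & rows$beta_anchor < 0
  rows$beta_anchor[rows$flipped] <- -rows$beta_anchor[rows$flipped]
  rows$beta_other[rows$flipped] <- -rows$beta_other[rows$flipped]
  rows$highlighted <- rows$rsid %in% oppSnps
  rows <- rows[order(rows$pos), , drop = FALSE]
  rownames(rows) <- NULL
  methods::new("LocusView", geneId = geneId, anchorTissue = anchorTissue,
               otherTissue = otherTissue, rows = rows)
}

#' Build the two-panel regional association plot of a locus view
#'
#' Two stacked panels (anchor tissue on top in red, other tissue below in
#' blue): beta on the y axis against chromosomal position, point opacity
#' scaled by -log10 p; highlighted (opp-multi-eQTL) SNPs are drawn as
#' triangles and appear in the legend.
#'
#' @param view a \linkS4class{LocusView}.
#' @return a ggplot object.
#' @export
locusPlot <- function(view) {
  rows <- locusRows(view)
  if (!nrow(rows)) stop("empty locus view")
  long <- rbind(
    data.frame(tissue = paste0(view@anchorTissue, " (anchor)"),
               pos = rows$pos, beta = rows$beta_anchor,
               mlog10p = rows$mlog10p_anchor, highlighted = rows$highlighted),
    data.frame(tissue = view@otherTissue,
               pos = rows$pos, beta = rows$beta_other,
               mlog10p = rows$mlog10p_other, highlighted = rows$highlighted)
  )
  long <- long[!is.na(long$beta), , drop = FALSE]
  long$tissue <- factor(long$tissue,
                        levels = c(paste0(view@anchorTissue, " (anchor)"), view@otherTissue))
  cols <- stats::setNames(c("#c0392b", "#2c5aa0"), levels(long$tissue))
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = pos / 1e6, y = beta, colour = tissue,
    alpha = mlog10p, shape = highlighted)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::scale_colour_manual(values = cols, guide = "none") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "opp-multi-eQTL SNP") +
    ggplot2::scale_alpha_continuous(name = expression(-log[10] * " p")) +
    ggplot2::facet_wrap(~tissue, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = expression(beta),
                  title = paste0(view@geneId, ": ", view@anchorTissue,
                                 " vs ", view@otherTissue)) +
    ggplot2::theme_bw(base_size = 10)
  p
}

#' Render a locus view to a PNG file
#'
#' Writes the \code{\link{locusPlot}} figure; rendering is deterministic for
#' fixed input (the cairo PNG device embeds no timestamps).
#'
#' @param view a \linkS4class{LocusView}.
#' @param path output file path (.png).
#' @param width,height,dpi figure geometry.
#' @return the path, invisibly.
#' @export
renderLocusFigure <- function(view, path, width = 7, height = 5, dpi = 150) {
  p <- locusPlot(view)
  grDevices::png(path, width = width, height = height, units = "in",
                 res = dpi, type = "cairo")
  print(p)
  grDevices::dev.off()
  invisible(path)
}

#' Write a locus view as TSV
#'
#' @param view a \linkS4class{LocusView}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeLocusView <- function(view, path) {
  data.table::fwrite(locusRows(view), path, sep = "\t", quote = FALSE)
  invisible(path)
}
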