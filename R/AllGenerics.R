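## Generics, accessors and show methods.

#' @rdname TissueTable-class
#' @param object a TissueTable (or other class, per method).
#' @export
setGeneric("tissueCode", function(object) standardGeneric("tissueCode"))

#' @rdname TissueTable-class
#' @export
setMethod("tissueCode", "TissueTable", function(object) object@tissue)

#' @rdname TissueTable-class
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' @rdname TissueTable-class
#' @export
setMethod("records", "TissueTable", function(object) object@records)

#' @rdname TopEqtlMap-class
#' @param object a TopEqtlMap.
#' @export
setGeneric("topEntries", function(object) standardGeneric("topEntries"))

#' @rdname TopEqtlMap-class
#' @export
setMethod("topEntries", "TopEqtlMap", function(object) object@entries)

#' @rdname HaplotypePanel-class
#' @param object a HaplotypePanel.
#' @export
setGeneric("variantKeys", function(object) standardGeneric("variantKeys"))

#' @rdname HaplotypePanel-class
#' @export
setMethod("variantKeys", "HaplotypePanel", function(object) object@variantKeys)

#' @rdname HaplotypePanel-class
#' @export
setGeneric("panelRsids", function(object) standardGeneric("panelRsids"))

#' @rdname HaplotypePanel-class
#' @export
setMethod("panelRsids", "HaplotypePanel", function(object) object@rsids)

#' @rdname HaplotypePanel-class
#' @export
setGeneric("haplotypes", function(object) standardGeneric("haplotypes"))

#' @rdname HaplotypePanel-class
#' @export
setMethod("haplotypes", "HaplotypePanel", function(object) object@haplotypes)

#' @rdname AnalysisTableSet-class
#' @param object an AnalysisTableSet.
#' @export
setGeneric("analysisTables", function(object) standardGeneric("analysisTables"))

#' @rdname AnalysisTableSet-class
#' @export
setMethod("analysisTables", "AnalysisTableSet", function(object) object@tables)

#' @rdname DesignationSets-class
#' @param object a DesignationSets.
#' @export
setGeneric("eqtlGenes", function(object) standardGeneric("eqtlGenes"))
#' @rdname DesignationSets-class
#' @export
setMethod("eqtlGenes", "DesignationSets", function(object) object@eqtlGenes)

#' @rdname DesignationSets-class
#' @export
setGeneric("topEqtlSnps", function(object) standardGeneric("topEqtlSnps"))
#' @rdname DesignationSets-class
#' @export
setMethod("topEqtlSnps", "DesignationSets", function(object) object@topEqtlSnps)

#' @rdname DesignationSets-class
#' @export
setGeneric("multiGenes", function(object) standardGeneric("multiGenes"))
#' @rdname DesignationSets-class
#' @export
setMethod("multiGenes", "DesignationSets", function(object) object@multiGenes)

#' @rdname DesignationSets-class
#' @export
setGeneric("multiSnps", function(object) standardGeneric("multiSnps"))
#' @rdname DesignationSets-class
#' @export
setMethod("multiSnps", "DesignationSets", function(object) object@multiSnps)

#' @rdname DesignationSets-class
#' @export
setGeneric("oppGenes", function(object) standardGeneric("oppGenes"))
#' @rdname DesignationSets-class
#' @export
setMethod("oppGenes", "DesignationSets", function(object) object@oppGenes)

#' @rdname DesignationSets-class
#' @export
setGeneric("oppSnps", function(object) standardGeneric("oppSnps"))
#' @rdname DesignationSets-class
#' @export
setMethod("oppSnps", "DesignationSets", function(object) object@oppSnps)

#' @rdname DesignationSets-class
#' @export
setGeneric("designationEvidence", function(object) standardGeneric("designationEvidence"))
#' @rdname DesignationSets-class
#' @export
setMethod("designationEvidence", "DesignationSets", function(object) object@evidence)

#' @rdname DistanceSample-class
#' @param object a DistanceSample.
#' @export
setGeneric("distances", function(object) standardGeneric("distances"))
#' @rdname DistanceSample-class
#' @export
setMethod("distances", "DistanceSample", function(object) object@pairs$tss_distance)

#' @rdname DistanceSample-class
#' @export
setGeneric("sharingCounts", function(object) standardGeneric("sharingCounts"))
#' @rdname DistanceSample-class
#' @export
setMethod("sharingCounts", "DistanceSample", function(object) object@pairs$sharing)

#' @rdname DistanceSample-class
#' @export
setGeneric("samplePairs", function(object) standardGeneric("samplePairs"))
#' @rdname DistanceSample-class
#' @export
setMethod("samplePairs", "DistanceSample", function(object) object@pairs)

#' @rdname GwasSnpSet-class
#' @param object a GwasSnpSet.
#' @export
setGeneric("gwasRsids", function(object) standardGeneric("gwasRsids"))
#' @rdname GwasSnpSet-class
#' @export
setMethod("gwasRsids", "GwasSnpSet", function(object) object@rsids)

#' @rdname LocusView-class
#' @param object a LocusView.
#' @export
setGeneric("locusRows", function(object) standardGeneric("locusRows"))
#' @rdname LocusView-class
#' @export
setMethod("locusRows", "LocusView", function(object) object@rows)

setMethod("show", "TissueTable", function(object) {
  cat("TissueTable:", object@tissue,
      if (length(object@organSystem) && nzchar(object@organSystem)) sprintf("(%s)", object@organSystem) else "",
      "\n  records:", nrow(object@records),
      "significant variant-gene pairs over", length(unique(object@records$gene_id)), "genes\n")
})

setMethod("show", "TopEqtlMap", function(object) {
  e <- object@entries
  cat("TopEqtlMap:", nrow(e), "gene x tissue top-eQTL entries |",
      length(unique(e$gene_id)), "genes,",
      length(unique(e$tissue)), "tissues,",
      length(unique(e$rsid)), "distinct SNPs\n")
})

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel (", object@population, "): ",
      length(object@variantKeys), " biallelic variants x ",
      ncol(object@haplotypes), " phased haplotypes\n", sep = "")
})

setMethod("show", "AnalysisTableSet", function(object) {
  tab <- table(factor(object@tables$status,
                      levels = c("excluded", "group_1a", "group_1b", "group_2a", "group_2b")))
  cat("AnalysisTableSet:", nrow(object@tables), "eligible-candidate tables",
      sprintf("(r2 threshold %.2f)\n", object@r2Threshold))
  print(tab)
})

setMethod("show", "DesignationSets", function(object) {
  cat("DesignationSets\n",
      sprintf("  eQTL-Genes: %d  top-eQTL-SNPs: %d\n", length(object@eqtlGenes), length(object@topEqtlSnps)),
      sprintf("  multi-eQTL-Genes: %d  multi-eQTL-SNPs: %d\n", length(object@multiGenes), length(object@multiSnps)),
      sprintf("  opp-multi-eQTL-Genes: %d  opp-multi-eQTL-SNPs: %d\n", length(object@oppGenes), length(object@oppSnps)))
})

setMethod("show", "OppositeFractionMatrix", function(object) {
  cat("OppositeFractionMatrix over", length(object@tissues), "tissues; mean fraction",
      sprintf("%.4f\n", mean(object@fraction[upper.tri(object@fraction)], na.rm = TRUE)))
})

setMethod("show", "DistanceSample", function(object) {
  cat("DistanceSample [", object@label, "]: ", nrow(object@pairs),
      " (gene, SNP) pairs; median |TSS distance| ",
      sprintf("%.0f bp\n", stats::median(abs(object@pairs$tss_distance))), sep = "")
})

setMethod("show", "GwasSnpSet", function(object) {
  cat("GwasSnpSet:", length(object@rsids), "rsids at p <", format(object@threshold), "\n")
})

setMethod("show", "AnnotationMatrix", function(object) {
  d <- dim(object@presence)
  cat("AnnotationMatrix:", d[1], "SNPs x", d[2], "cell lines x", d[3], "marks;",
      sum(object@availability), "available (cell, mark) combinations\n")
})

setMethod("show", "LocusView", function(object) {
  cat("LocusView:", object@geneId, "|", object@anchorTissue, "(anchor) vs",
      object@otherTissue, "|", nrow(object@rows), "SNPs,",
      sum(object@rows$highlighted), "highlighted\n")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes x", object@nTissues, "tissues |",
      object@nBlocks, "LD blocks x", object@snpsPerBlock, "SNPs,",
      object@nHaplotypes, "haplotypes | theta_opp =", object@thetaOpp,
      "| seed =", object@seed, "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@genes), "genes (",
      sum(object@genes$label == "opposite"), "opposite,",
      sum(object@genes$label == "concordant"), "concordant,",
      sum(object@genes$label == "single_tissue"), "single-tissue )\n")
})
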