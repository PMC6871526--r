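## TSS-distance distributions per SNP class, sharing-matched subsampling,
## kurtosis statistic and the resampling enrichment p-value.

#' Construct a DistanceSample
#'
#' @param label SNP-class name.
#' @param pairs data.frame with columns gene_id, rsid, tss_distance, sharing.
#' @return a \linkS4class{DistanceSample}.
#' @export
distanceSample <- function(label, pairs) {
  methods::new("DistanceSample", label = label,
               pairs = as.data.frame(pairs, stringsAsFactors = FALSE))
}

#' Build the TSS-distance samples of every SNP class
#'
#' Assembles, as unique (gene, SNP) pairs, the four SNP classes whose
#' TSS-distance distributions are compared: all pairs with any significant
#' eQTL signal, the top-eQTL pairs, the multi-eQTL pairs and the
#' opp-multi-eQTL pairs. Each pair carries its signed TSS distance and its
#' number of sharing tissues (tissues in which the same gene-SNP pair is
#' significant).
#'
#' @param designations a \linkS4class{DesignationSets}.
#' @param tables named list of (filtered) \linkS4class{TissueTable}.
#' @param top the cohort's \linkS4class{TopEqtlMap}.
#' @return named list of \linkS4class{DistanceSample}: any, top, multi, opp.
#' @export
buildDistanceSamples <- function(designations, tables, top) {
  pieces <- lapply(tables, function(tt) {
    r <- records(tt)
    data.table::data.table(gene_id = r$gene_id, rsid = r$rsid,
                           tss_distance = r$tss_distance)
  })
  all <- data.table::rbindlist(pieces)
  sharing <- all[, list(sharing = .N, tss_distance = tss_distance[1L]),
                 by = c("gene_id", "rsid")]
  data.table::setkey(sharing, gene_id, rsid)
  fromPairs <- function(label, g, s) {
    key <- unique(data.table::data.table(gene_id = g, rsid = s))
    m <- sharing[key, on = c("gene_id", "rsid"), nomatch = NULL]
    distanceSample(label, data.frame(gene_id = m$gene_id, rsid = m$rsid,
                                     tss_distance = m$tss_distance,
                                     sharing = m$sharing))
  }
  e <- topEntries(top)
  ev <- designationEvidence(designations)
  evOpp <- ev[ev$group == "1a", , drop = FALSE]
  list(
    any = distanceSample("any_eqtl", data.frame(
      gene_id = sharing$gene_id, rsid = sharing$rsid,
      tss_distance = sharing$tss_distance, sharing = sharing$sharing)),
    top = fromPairs("top_eqtl", e$gene_id, e$rsid),
    multi = fromPairs("multi_eqtl", c(ev$gene_id, ev$gene_id), c(ev$snp_x, ev$snp_y)),
    opp = fromPairs("opp_multi_eqtl", c(evOpp$gene_id, evOpp$gene_id),
                    c(evOpp$snp_x, evOpp$snp_y))
  )
}

## internal: stratified without-replacement sampling of source indices so the
## sampled stratum counts match the target counts (capped at availability).
.matchedSample <- function(sourceStrata, targetCounts) {
  idx <- integer(0)
  deficit <- integer(0)
  for (k in names(targetCounts)) {
    need <- targetCounts[[k]]
    avail <- sourceStrata[[k]]
    nAvail <- length(avail)
    take <- min(need, nAvail)
    if (take > 0L) idx <- c(idx, avail[sample.int(nAvail, take)])
    if (take < need) deficit[k] <- need - take
  }
  list(idx = idx, deficit = deficit)
}

#' Sharing-count-matched subsample of the multi pairs
#'
#' Draws, without replacement, a subset of the multi-eQTL pairs whose
#' distribution of sharing-tissue counts matches that of the opp pairs: for
#' each sharing-count value k, the number of opp pairs with count k is drawn
#' from the multi pairs with count k (capped at availability; any deficit is
#' recorded in the \code{"deficit"} attribute).
#'
#' @param multi,opp \linkS4class{DistanceSample} objects carrying sharing counts.
#' @param seed integer seed; identical seeds give identical subsamples.
#' @return a \linkS4class{DistanceSample} labelled "multi_sharing_adjusted".
#' @export
sharingMatchedSubsample <- function(multi, opp, seed) {
  mp <- samplePairs(multi)
  strata <- split(seq_len(nrow(mp)), mp$sharing)
  need <- table(sharingCounts(opp))
  res <- withSeed(seed, .matchedSample(strata, as.list(need)))
  out <- distanceSample("multi_sharing_adjusted", mp[res$idx, , drop = FALSE])
  attr(out, "deficit") <- res$deficit
  out
}

#' Resampling p-value for TSS enrichment by kurtosis
#'
#' Tests whether the opp-multi-eQTL pairs are more concentrated at the TSS
#' than sharing-matched subsamples of the multi-eQTL pairs. The statistic is
#' the Pearson sample kurtosis of the raw signed TSS distances; for each
#' replicate a fresh sharing-matched subsample of the multi pairs is drawn
#' and its kurtosis computed. The one-sided p-value is the fraction of
#' replicates with kurtosis at least the observed opp kurtosis; when no
#' replicate reaches it the strict bound p < 1/nRep is reported.
#'
#' @param opp,multi \linkS4class{DistanceSample} objects.
#' @param nRep number of resampling replicates (default 10000).
#' @param seed master seed; replicate i uses an independent derived stream.
#' @return list: observed kurtosis, pvalue, bound (TRUE when p is the strict
#'   bound), pLabel, nRep, replicates (the replicate kurtosis values).
#' @export
tssEnrichmentPvalue <- function(opp, multi, nRep = 10000, seed = 1L) {
  observed <- sampleKurtosis(distances(opp))
  mp <- samplePairs(multi)
  strata <- split(seq_len(nrow(mp)), mp$sharing)
  need <- as.list(table(sharingCounts(opp)))
  reps <- vapply(seq_len(nRep), function(i) {
    res <- withSeed(subSeed(seed, i), .matchedSample(strata, need))
    sampleKurtosis(mp$tss_distance[res$idx])
  }, 0)
  c(list(observed = observed), exceedanceP(reps, observed), list(replicates = reps))
}

#' Kernel-density ratio at the TSS between two distance samples
#'
#' Gaussian kernel density estimates of both TSS-distance samples, evaluated
#' at distance 0 (the TSS); bandwidths follow Silverman's rule
#' (\code{\link[stats]{bw.nrd0}}) and are recorded as attributes. The value
#' returned is density_b(0) / density_a(0), so a ratio above 1 means sample b
#' is more TSS-concentrated than sample a.
#'
#' @param a,b numeric distance vectors or \linkS4class{DistanceSample} objects.
#' @return the density ratio, with attributes \code{bw_a}, \code{bw_b}.
#' @export
densityRatioAtTss <- function(a, b) {
  xa <- if (methods::is(a, "DistanceSample")) distances(a) else as.numeric(a)
  xb <- if (methods::is(b, "DistanceSample")) distances(b) else as.numeric(b)
  if (!length(xa) || !length(xb)) stop("both samples must be non-empty")
  kdeAt0 <- function(x) {
    bw <- stats::bw.nrd0(x)
    list(f = mean(stats::dnorm(x / bw)) / bw, bw = bw)
  }
  fa <- kdeAt0(xa); fb <- kdeAt0(xb)
  out <- fb$f / fa$f
  attr(out, "bw_a") <- fa$bw
  attr(out, "bw_b") <- fb$bw
  out
}
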