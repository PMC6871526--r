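## Shared fixture builders: tiny tables, toy panels and a cached default
## synthetic cohort. Everything is generated in code at test time.

## write a significant-pair TSV in the input dialect
writeEqtlTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

## rows in the on-disk dialect; betas chosen as exact binary fractions so
## identity reads can be checked bit-exactly
tinyEqtlRows <- function() {
  data.frame(
    gene_id = c("G1", "G1", "G2"),
    variant_id = c("1_1000_A_G_b37", "1_2000_C_T_b37", "1_3000_G_A_b37"),
    rs_id_dbSNP = c("rs1", "rs2", "rs3"),
    tss_distance = c(-500L, 500L, 0L),
    slope = c(0.5, -0.25, 0.125),
    pval_nominal = c(1e-8, 1e-6, 1e-4),
    stringsAsFactors = FALSE
  )
}

## a TissueTable straight from records columns
tinyTable <- function(tissue, gene_id, variant_key, rsid, beta, pval,
                      tss_distance = 0) {
  new("TissueTable", tissue = tissue, organSystem = "",
      records = data.frame(gene_id = gene_id, variant_key = variant_key,
                           rsid = rsid, beta = beta, pval = pval,
                           tss_distance = tss_distance,
                           stringsAsFactors = FALSE))
}

## panel from an explicit variants x haplotypes 0/1 matrix
toyPanel <- function(H, rsids = sprintf("rs%d", seq_len(nrow(H))),
                     pos = seq_len(nrow(H)) * 1000L, chrom = "1") {
  ref <- rep("A", nrow(H)); alt <- rep("G", nrow(H))
  new("HaplotypePanel",
      variantKeys = paste(chrom, pos, ref, alt, "b37", sep = "_"),
      rsids = rsids, chrom = rep(chrom, nrow(H)), pos = as.integer(pos),
      haplotypes = matrix(as.integer(H), nrow(H)), population = "EUR")
}

## a DistanceSample with auto gene/rsid labels
toyDistanceSample <- function(label, tss, sharing = rep(1L, length(tss)),
                              rsid = sprintf("rs%d", seq_along(tss))) {
  distanceSample(label, data.frame(gene_id = sprintf("G%d", seq_along(tss)),
                                   rsid = rsid, tss_distance = tss,
                                   sharing = sharing))
}

## default synthetic cohort with the whole pipeline run, cached per session
defaultCohortPipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simConfig(seed = 42)
    co <- simulateCohort(cfg)
    filt <- lapply(co$tables, filterVariants, panelKeys = variantKeys(co$panel))
    top <- extractTopEqtl(filt)
    ats <- classifyTissuePairs(top, filt, co$panel)
    des <- aggregateDesignations(ats, top)
    cache <<- c(co, list(config = cfg, filtered = filt, top = top,
                         ats = ats, designations = des))
    cache
  }
})

## independent brute-force re-derivation of group assignments, written
## deliberately naively (per-gene, per-pair dictionary lookups and scalar
## ldR2 calls) as the oracle for the vectorized classifier
bruteForceClassify <- function(top, tables, panel, r2Threshold = 0.8) {
  e <- topEntries(top)
  tissues <- sort(names(tables))
  recs <- lapply(tables, records)
  out <- list()
  for (g in unique(e$gene_id)) {
    eg <- e[e$gene_id == g, ]
    present <- sort(intersect(tissues, eg$tissue))
    if (length(present) < 2) next
    for (i in seq_len(length(present) - 1)) {
      for (j in seq(i + 1, length(present))) {
        tx <- present[i]; ty <- present[j]
        rx <- eg[eg$tissue == tx, ]; ry <- eg[eg$tissue == ty, ]
        getBeta <- function(tissue, key) {
          r <- recs[[tissue]]
          b <- r$beta[r$gene_id == g & r$variant_key == key]
          if (length(b)) b[1] else 0
        }
        bxx <- rx$beta; byy <- ry$beta
        bxy <- getBeta(ty, rx$variant_key)
        byx <- getBeta(tx, ry$variant_key)
        eligible <- rx$rsid == ry$rsid || bxy != 0 || byx != 0
        status <- if (!eligible) "excluded" else {
          oppo <- (bxx * bxy <= 0) && (byx * byy <= 0)
          r2 <- if (rx$rsid == ry$rsid) 1 else ldR2(rx$rsid, ry$rsid, panel)
          high <- !is.na(r2) && r2 > r2Threshold
          paste0("group_", if (oppo) "1" else "2", if (high) "a" else "b")
        }
        out[[length(out) + 1]] <- data.frame(
          gene_id = g, tissue_x = tx, tissue_y = ty,
          snp_x = rx$rsid, snp_y = ry$rsid, status = status,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
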