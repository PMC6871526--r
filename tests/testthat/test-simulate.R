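test_that("cohorts are byte-identical across runs under one seed", {
  cfg <- simConfig(seed = 123, nGenes = 40L, nBlocks = 30L)
  d1 <- file.path(tempdir(), "cohort_a"); d2 <- file.path(tempdir(), "cohort_b")
  p1 <- writeCohort(simulateCohort(cfg), d1)
  p2 <- writeCohort(simulateCohort(cfg), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  ## a different seed changes the outputs
  d3 <- file.path(tempdir(), "cohort_c")
  p3 <- writeCohort(simulateCohort(simConfig(seed = 124, nGenes = 40L, nBlocks = 30L)), d3)
  expect_false(identical(readLines(p1[["panel"]]), readLines(p3[["panel"]])))
})

test_that("panel LD structure hits the block targets", {
  ## zero mutation rate: perfect within-block correlation
  cfgPerfect <- simConfig(seed = 5, nBlocks = 10L, snpsPerBlock = 4L,
                          blockR2Target = 1)
  pp <- simulatePanel(cfgPerfect)
  H <- haplotypes(pp)
  blocks <- rep(1:10, each = 4)
  for (b in 1:3) {
    idx <- which(blocks == b)
    for (i in idx[-1]) expect_equal(cor(H[idx[1], ], H[i, ])^2, 1)
  }

  ## default target: mean realized within-block r2 within +/- 0.1
  co <- defaultCohortPipeline()
  Hd <- haplotypes(co$panel)
  bl <- attr(co$panel, "blocks")
  set.seed(2)
  wr2 <- replicate(300, {
    b <- sample(max(bl), 1)
    ij <- sample(which(bl == b), 2)
    cor(Hd[ij[1], ], Hd[ij[2], ])^2
  })
  expect_equal(mean(wr2), co$config@blockR2Target, tolerance = 0.1)

  ## cross-block r2 is near the independence expectation 1/(nHap - 1)
  xr2 <- replicate(300, {
    bb <- sample(max(bl), 2)
    i <- sample(which(bl == bb[1]), 1); j <- sample(which(bl == bb[2]), 1)
    cor(Hd[i, ], Hd[j, ])^2
  })
  expect_lt(mean(xr2), 3 / (ncol(Hd) - 1))

  ## allele frequencies inside [0.05, 0.95]
  f <- rowMeans(Hd)
  expect_true(all(f >= 0.05 & f <= 0.95))
})

test_that("simulated tables re-load losslessly and respect the sign plan", {
  co <- defaultCohortPipeline()
  t1 <- co$tables[[1]]
  f <- tempfile(fileext = ".tsv")
  writeTissueTable(t1, f)
  t2 <- loadSignificantPairs(f, tissue = tissueCode(t1))
  expect_identical(records(t2), records(t1))

  ## opposite genes: causal record signs differ exactly in the planted pair
  g <- co$truth@genes
  for (i in which(g$label == "opposite")[1:5]) {
    recA <- records(co$tables[[g$tissue_a[i]]])
    recB <- records(co$tables[[g$tissue_b[i]]])
    bA <- recA$beta[recA$gene_id == g$gene_id[i] & recA$rsid == g$causal_rsid[i]]
    bB <- recB$beta[recB$gene_id == g$gene_id[i] & recB$rsid == g$causal_rsid[i]]
    expect_lt(bA * bB, 0)
  }
  ## single-tissue genes appear in exactly one tissue
  for (i in which(g$label == "single_tissue")[1:5]) {
    n <- sum(vapply(co$tables, function(tt)
      any(records(tt)$gene_id == g$gene_id[i]), TRUE))
    expect_identical(n, 1L)
  }
})

test_that("annotation boost and availability behave at both extremes", {
  cfg0 <- simConfig(seed = 31, annotationBoost = 0)
  co0 <- simulateCohort(cfg0)
  sc <- rowMeans(co0$annotations@presence[, co0$annotations@availability[, "DNase"], "DNase"])
  fl <- co0$truth@snps$annotation_flag[match(names(sc), co0$truth@snps$rsid)]
  ## without boost, flagged and background SNP rates differ only by noise
  if (sum(fl) > 10) {
    expect_lt(abs(mean(sc[fl]) - mean(sc[!fl])), 0.12)
  }
  ## validity enforces presence only where available (constructed objects pass)
  expect_true(validObject(co0$annotations))
})

test_that("GWAS partner emission respects rho and verified LD", {
  ## rho = 1: every planted causal SNP of an opposite gene is hit
  cfg1 <- simConfig(seed = 61, gwasRho = 1, gwasBackgroundN = 0L, gwasNonsigN = 0L)
  panel <- simulatePanel(cfg1)
  eq <- simulateEqtlTables(cfg1, panel)
  gwas <- simulateGwasCatalog(cfg1, panel, eq$truth)
  expect_true(all(gwas[["P-VALUE"]] < 5e-8))
  minP <- tapply(gwas[["P-VALUE"]], gwas$SNPS, min)[unique(gwas$SNPS)]
  gw <- new("GwasSnpSet", rsids = unique(gwas$SNPS),
            pvalues = stats::setNames(as.numeric(minP), unique(gwas$SNPS)),
            threshold = 5e-8)
  causal <- eq$truth@genes$causal_rsid[eq$truth@genes$label == "opposite"]
  ov <- classLdOverlap(causal, gw, panel)
  expect_equal(ov$proportion, 1)
  ## every emitted partner verified in LD (> 0.8) with some planted causal SNP
  for (s in unique(gwas$SNPS)) {
    r2 <- vapply(causal, function(c) {
      v <- ldR2(s, c, panel); if (is.na(v)) 0 else v
    }, 0)
    expect_gt(max(r2), 0.8)
  }

  ## rho = 0: only background rows remain
  cfg0 <- simConfig(seed = 61, gwasRho = 0, gwasBackgroundN = 10L, gwasNonsigN = 5L)
  g0 <- simulateGwasCatalog(cfg0, panel, eq$truth)
  expect_equal(sum(g0[["P-VALUE"]] < 5e-8), 10L)
})
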