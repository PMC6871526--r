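test_that("per-tissue counts equal a naive recount of the evidence lists", {
  co <- defaultCohortPipeline()
  ts <- perTissueCounts(co$designations, co$top)
  s <- ts@summary
  e <- topEntries(co$top)
  ev <- designationEvidence(co$designations)
  for (t in s$tissue) {
    expect_identical(s$n_eqtl_genes[s$tissue == t],
                     length(unique(e$gene_id[e$tissue == t])))
    inPair <- ev$tissue_x == t | ev$tissue_y == t
    expect_identical(s$n_multi_genes[s$tissue == t],
                     length(unique(ev$gene_id[inPair])))
    expect_identical(s$n_opp_genes[s$tissue == t],
                     length(unique(ev$gene_id[inPair & ev$group == "1a"])))
  }
  expect_true(all(s$n_opp_genes <= s$n_multi_genes))
  expect_true(all(s$n_multi_genes <= s$n_eqtl_genes))
  ratios <- unlist(s[, c("multi_over_eqtl", "opp_over_eqtl", "opp_over_multi")])
  expect_true(all(is.na(ratios) | (ratios >= 0 & ratios <= 1)))
})

test_that("a single-tissue cohort has no multi/opp counts; equal counts give CV 0", {
  tt <- tinyTable("ONLY", gene_id = c("G1", "G2"),
                  variant_key = c("1_100_A_G_b37", "1_200_C_T_b37"),
                  rsid = c("rs1", "rs2"), beta = c(0.5, -0.5), pval = c(1e-8, 1e-8))
  top <- extractTopEqtl(list(ONLY = tt))
  panel <- toyPanel(matrix(rbinom(40, 1, 0.5), nrow = 2))
  des <- aggregateDesignations(classifyTissuePairs(top, list(ONLY = tt), panel), top)
  ts <- perTissueCounts(des, top)
  expect_identical(ts@summary$n_multi_genes, 0L)
  expect_identical(ts@summary$n_opp_genes, 0L)

  ## identical counts across tissues -> CV = 0
  tabs <- lapply(c("A", "B", "C"), function(t)
    tinyTable(t, gene_id = c("G1", "G2"),
              variant_key = c("1_100_A_G_b37", "1_200_C_T_b37"),
              rsid = c("rs1", "rs2"), beta = c(0.5, 0.5), pval = c(1e-8, 1e-8)))
  names(tabs) <- c("A", "B", "C")
  top3 <- extractTopEqtl(tabs)
  des3 <- aggregateDesignations(classifyTissuePairs(top3, tabs, panel), top3)
  ts3 <- perTissueCounts(des3, top3)
  expect_equal(unname(ts3@cv["n_eqtl_genes"]), 0)
})

test_that("opposite fractions match an exhaustive loop and are order-invariant", {
  co <- defaultCohortPipeline()
  ofm <- oppositeFractionMatrix(co$filtered)
  f <- ofm@fraction
  expect_true(isTRUE(all.equal(f, t(f))))
  expect_true(all(diag(f) == 0))
  ## exhaustive re-comparison for a few pairs + integrality of the counts
  tissues <- ofm@tissues
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    ri <- records(co$filtered[[tissues[pair[1]]]])
    rj <- records(co$filtered[[tissues[pair[2]]]])
    ki <- paste(ri$gene_id, ri$variant_key)
    kj <- paste(rj$gene_id, rj$variant_key)
    shared <- intersect(ki, kj)
    opp <- sum(ri$beta[match(shared, ki)] * rj$beta[match(shared, kj)] < 0)
    expect_identical(ofm@nShared[pair[1], pair[2]], length(shared))
    if (length(shared)) {
      expect_equal(f[pair[1], pair[2]], opp / length(shared))
      expect_equal(f[pair[1], pair[2]] * ofm@nShared[pair[1], pair[2]], opp)
    }
  }
  ## permuting the input tissue order relabels but does not change values
  ofm2 <- oppositeFractionMatrix(rev(co$filtered))
  expect_identical(ofm2@fraction[tissues, tissues], f)
})

test_that("degenerate beta tables give fractions 0 and 1", {
  tt <- tinyTable("A", gene_id = c("G1", "G2"),
                  variant_key = c("1_100_A_G_b37", "1_200_C_T_b37"),
                  rsid = c("rs1", "rs2"), beta = c(0.5, -0.25), pval = c(1e-8, 1e-8))
  same <- tinyTable("B", records(tt)$gene_id, records(tt)$variant_key,
                    records(tt)$rsid, records(tt)$beta, records(tt)$pval)
  neg <- tinyTable("C", records(tt)$gene_id, records(tt)$variant_key,
                   records(tt)$rsid, -records(tt)$beta, records(tt)$pval)
  ofm <- oppositeFractionMatrix(list(A = tt, B = same, C = neg))
  expect_equal(ofm@fraction["A", "B"], 0)
  expect_equal(ofm@fraction["A", "C"], 1)
})

test_that("tissue clustering is deterministic and respects planted structure", {
  ## two identical rows merge first at height 0
  f <- matrix(c(0, 0.1, 0.1,
                0.1, 0, 0,
                0.1, 0, 0), 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  ofm <- new("OppositeFractionMatrix", tissues = LETTERS[1:3],
             fraction = f, nShared = matrix(10L, 3, 3))
  hc <- clusterTissues(ofm)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[hc$merge[1, ] * -1], c("B", "C"))
  ## merge heights equal hand-computed Euclidean linkage
  expect_equal(sort(hc$height),
               sort(c(0, sqrt(sum((f["A", ] - f["B", ])^2)))))

  ## block-structured matrix separates the planted groups
  g1 <- 1:3; g2 <- 4:6
  fb <- matrix(0.3, 6, 6); fb[g1, g1] <- 0.05; fb[g2, g2] <- 0.05; diag(fb) <- 0
  dimnames(fb) <- list(LETTERS[1:6], LETTERS[1:6])
  ofb <- new("OppositeFractionMatrix", tissues = LETTERS[1:6],
             fraction = fb, nShared = matrix(10L, 6, 6))
  hcb <- clusterTissues(ofb)
  expect_setequal(split(hcb$labels, cutree(hcb, 2)) |> lapply(sort) |> unname(),
                  list(c("A", "B", "C"), c("D", "E", "F")))
  ## deterministic across runs, and exportable as newick
  expect_identical(clusterTissues(ofb)$merge, hcb$merge)
  expect_match(dendrogramNewick(hcb), "^\\(.*\\);$")
})

test_that("p-value deviation histograms are normalized on a shared grid", {
  co <- defaultCohortPipeline()
  pv <- pvalueDeviationDensity(co$ats)
  expect_equal(sum(pv$multi), 1)
  expect_equal(sum(pv$opp), 1)
  expect_equal(sum(pv$difference), 0)
  ## mass satisfies -log10 p1 >= -log10 p2 (on/under the x = y diagonal)
  nb <- nrow(pv$multi)
  upper <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  expect_equal(sum(pv$multi[upper]), 0)

  ## a pair with equal p-values lands on the diagonal bin
  one <- new("AnalysisTableSet", r2Threshold = 0.8, nGenes = 1L, nTissues = 2L,
             tables = data.frame(gene_id = "G1", tissue_x = "A", tissue_y = "B",
                                 snp_x = "rs1", snp_y = "rs1",
                                 beta_xx = 1, beta_xy = -1, beta_yx = 1, beta_yy = -1,
                                 pval_x = 1e-4, pval_y = 1e-4, r2 = 1,
                                 direction = "opposite", status = "group_1a"))
  pv1 <- pvalueDeviationDensity(one)
  idx <- which(pv1$opp == 1, arr.ind = TRUE)
  expect_equal(unname(idx[1, "row"]), unname(idx[1, "col"]))
})
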