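test_that("single analysis tables collect betas by lookup", {
  tA <- tinyTable("A", gene_id = c("G1", "G2"), rsid = c("rs1", "rs2"),
                  variant_key = c("1_100_A_G_b37", "1_200_C_T_b37"),
                  beta = c(0.5, 0.3), pval = c(1e-8, 1e-7))
  tB <- tinyTable("B", gene_id = "G1", rsid = "rs1",
                  variant_key = "1_100_A_G_b37", beta = -0.4, pval = 1e-5)
  tabs <- list(A = tA, B = tB)
  top <- extractTopEqtl(tabs)

  ## gene significant in only one tissue -> ineligible
  row <- buildAnalysisTable("G2", "A", "B", top, tabs)
  expect_identical(row$status, "ineligible")

  ## identical top SNP in both tissues -> beta_xy == beta_yy by construction
  row <- buildAnalysisTable("G1", "A", "B", top, tabs)
  expect_identical(row$status, "pending")
  expect_identical(row$beta_xy, row$beta_yy)
  expect_identical(row$beta_yx, row$beta_xx)
})

test_that("bulk tables equal direct dictionary lookups on a small fixture", {
  set.seed(3)
  genes <- sprintf("G%d", 1:4); tissues <- c("A", "B", "C")
  H <- matrix(rbinom(6 * 40, 1, 0.5), nrow = 6)
  panel <- toyPanel(H)
  tabs <- lapply(tissues, function(t) {
    pick <- sort(sample(6, 4))
    tinyTable(t, gene_id = sample(genes, 4, replace = FALSE),
              variant_key = variantKeys(panel)[pick],
              rsid = panelRsids(panel)[pick],
              beta = runif(4, 0.2, 1) * sample(c(-1, 1), 4, replace = TRUE),
              pval = 10^-sample(4:9, 4, replace = TRUE))
  })
  names(tabs) <- tissues
  top <- extractTopEqtl(tabs)
  ats <- classifyTissuePairs(top, tabs, panel)
  t <- analysisTables(ats)
  for (i in seq_len(nrow(t))) {
    want <- buildAnalysisTable(t$gene_id[i], t$tissue_x[i], t$tissue_y[i], top, tabs)
    expect_equal(t[i, c("snp_x", "snp_y", "beta_xx", "beta_xy", "beta_yx", "beta_yy")],
                 want[, c("snp_x", "snp_y", "beta_xx", "beta_xy", "beta_yx", "beta_yy")],
                 ignore_attr = TRUE)
  }
})

test_that("eligibility follows the identical-or-cross-significant rule", {
  base <- data.frame(snp_x = "rs1", snp_y = "rs2",
                     beta_xx = 0.4, beta_yy = 0.6, beta_xy = 0, beta_yx = 0)
  expect_false(eligibility(base))                        # neither cross-significant
  expect_true(eligibility(transform(base, snp_y = "rs1")))  # identical SNP
  expect_true(eligibility(transform(base, beta_xy = -0.2)))  # one cross-significant
  expect_true(eligibility(transform(base, beta_yx = 0.1)))
})

test_that("direction rule matches exhaustive sign-pattern enumeration", {
  ## identical-SNP sign flip and same-direction base cases
  flip <- data.frame(beta_xx = 0.5, beta_xy = -0.3, beta_yx = 0.5, beta_yy = -0.3)
  expect_identical(classifyDirection(flip), "opposite")
  same <- data.frame(beta_xx = 0.5, beta_xy = 0.3, beta_yx = 0.5, beta_yy = 0.3)
  expect_identical(classifyDirection(same), "same")

  ## all 3^2 sign patterns of the cross betas against an independent
  ## enumeration of the rule "both products non-positive"
  for (sxy in c(-0.2, 0, 0.2)) {
    for (syx in c(-0.1, 0, 0.1)) {
      row <- data.frame(beta_xx = 0.4, beta_xy = sxy, beta_yx = syx, beta_yy = 0.6)
      want <- if (0.4 * sxy <= 0 && syx * 0.6 <= 0) "opposite" else "same"
      expect_identical(classifyDirection(row), want)
    }
  }
})

test_that("group assignment crosses direction with the strict LD threshold", {
  expect_identical(assignGroup("opposite", 1), "group_1a")      # identical SNP
  expect_identical(assignGroup("opposite", 0.5), "group_1b")
  expect_identical(assignGroup("same", 0.95), "group_2a")
  expect_identical(assignGroup("same", 0.8), "group_2b")        # strict ">"
  expect_identical(assignGroup("opposite", NA_real_), "group_1b")  # undefined r2
})

test_that("designations aggregate evidence with nested sets", {
  ## one gene opposite between exactly one pair of 5 tissues
  tissues <- LETTERS[1:5]
  betas <- c(A = 0.5, B = 0.5, C = 0.5, D = 0.5, E = -0.5)
  tabs <- lapply(tissues, function(t) {
    tinyTable(t, gene_id = "G1", variant_key = "1_1000_A_G_b37",
              rsid = "rs1", beta = unname(betas[t]), pval = 1e-8)
  })
  names(tabs) <- tissues
  panel <- toyPanel(matrix(rbinom(40, 1, 0.5), nrow = 1))
  top <- extractTopEqtl(tabs)
  ats <- classifyTissuePairs(top, tabs, panel)
  des <- aggregateDesignations(ats, top)
  expect_identical(oppGenes(des), "G1")
  ev <- designationEvidence(des)
  expect_equal(sum(ev$group == "1a"), 4L)  # E vs each concordant tissue
  expect_true(all(ev$tissue_y[ev$group == "1a"] == "E" |
                    ev$tissue_x[ev$group == "1a"] == "E"))
})

test_that("null cohorts yield no opposite designations", {
  cfg <- simConfig(seed = 9, nGenes = 80, thetaOpp = 0)
  co <- simulateCohort(cfg)
  filt <- lapply(co$tables, filterVariants, panelKeys = variantKeys(co$panel))
  top <- extractTopEqtl(filt)
  des <- aggregateDesignations(classifyTissuePairs(top, filt, co$panel), top)
  expect_length(oppGenes(des), 0)
  expect_length(oppSnps(des), 0)
})

test_that("classifier agrees with the naive brute-force implementation", {
  co <- defaultCohortPipeline()
  got <- analysisTables(co$ats)
  want <- bruteForceClassify(co$top, co$filtered, co$panel)
  key <- function(d) paste(d$gene_id, d$tissue_x, d$tissue_y)
  expect_setequal(key(got), key(want))
  m <- match(key(want), key(got))
  expect_identical(got$status[m], want$status)
  expect_identical(got$snp_x[m], want$snp_x)
  ## partition: every eligible table gets exactly one group
  expect_true(all(got$status %in% c("excluded", "group_1a", "group_1b",
                                    "group_2a", "group_2b")))
})

test_that("subset chains, symmetry and threshold monotonicity hold", {
  co <- defaultCohortPipeline()
  des <- co$designations
  expect_true(all(oppGenes(des) %in% multiGenes(des)))
  expect_true(all(multiGenes(des) %in% eqtlGenes(des)))
  expect_true(all(oppSnps(des) %in% multiSnps(des)))
  expect_true(all(multiSnps(des) %in% topEqtlSnps(des)))

  ## symmetry: swapping the tissue roles flips labels but not the call
  t <- analysisTables(co$ats)
  set.seed(2)
  for (i in sample(which(t$status != "excluded"), 25)) {
    sw <- buildAnalysisTable(t$gene_id[i], t$tissue_y[i], t$tissue_x[i],
                             co$top, co$filtered)
    expect_identical(sw$beta_xx, t$beta_yy[i])
    expect_identical(sw$beta_xy, t$beta_yx[i])
    dirSw <- classifyDirection(sw)
    expect_identical(dirSw, t$direction[i])
  }

  ## monotonicity: lowering the r2 threshold can only grow the sets
  sizes <- sapply(c(0.8, 0.5, 0), function(th) {
    d <- aggregateDesignations(
      classifyTissuePairs(co$top, co$filtered, co$panel, r2Threshold = th), co$top)
    c(length(multiSnps(d)), length(oppSnps(d)),
      length(multiGenes(d)), length(oppGenes(d)))
  })
  expect_true(all(diff(t(sizes)) >= 0))
})
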