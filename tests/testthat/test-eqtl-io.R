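test_that("a well-formed table reads identically and round-trips", {
  rows <- tinyEqtlRows()
  tt <- loadSignificantPairs(writeEqtlTsv(rows), tissue = "WHLBLD",
                             organSystem = "hematologic")
  expect_s4_class(tt, "TissueTable")
  expect_equal(nrow(records(tt)), 3L)
  expect_identical(records(tt)$beta, rows$slope)      # bit-exact identity read
  expect_identical(records(tt)$pval, rows$pval_nominal)
  expect_identical(attr(tt, "rejected"), 0L)

  out <- tempfile(fileext = ".tsv")
  writeTissueTable(tt, out)
  tt2 <- loadSignificantPairs(out, tissue = "WHLBLD")
  expect_identical(records(tt2), records(tt))
})

test_that("invalid rows are rejected with a count; structural errors are hard", {
  rows <- tinyEqtlRows()
  rows$pval_nominal[2] <- 0                       # p must be > 0
  expect_message(
    tt <- loadSignificantPairs(writeEqtlTsv(rows), tissue = "T"),
    "rejected")
  expect_identical(attr(tt, "rejected"), 1L)
  expect_equal(nrow(records(tt)), 2L)

  rows <- tinyEqtlRows()
  rows$slope[1] <- 0                              # 0 encodes "not significant"
  expect_message(tt <- loadSignificantPairs(writeEqtlTsv(rows), tissue = "T"))
  expect_identical(attr(tt, "rejected"), 1L)

  dup <- rbind(tinyEqtlRows(), tinyEqtlRows()[1, ])
  expect_error(loadSignificantPairs(writeEqtlTsv(dup), tissue = "T"), "duplicated")

  noCol <- tinyEqtlRows(); noCol$slope <- NULL
  expect_error(loadSignificantPairs(writeEqtlTsv(noCol), tissue = "T"), "slope")

  empty <- tinyEqtlRows()[0, ]
  expect_error(loadSignificantPairs(writeEqtlTsv(empty), tissue = "T"), "zero")
})

test_that("panel filtering applies all three removal rules and is idempotent", {
  tt <- tinyTable("T",
                  gene_id = c("G1", "G1", "G1", "G2", "G2"),
                  variant_key = c("1_100_A_G_b37", "1_200_AT_G_b37",  # indel
                                  "1_300_C_T_b37", "1_400_G_A_b37",
                                  "1_500_T_C_b37"),
                  rsid = sprintf("rs%d", 1:5),
                  beta = c(0.5, 0.5, -0.5, 0.25, 0.25),
                  pval = rep(1e-6, 5))
  panelKeys <- c("1_100_A_G_b37", "1_200_AT_G_b37", "1_300_C_T_b37", "1_400_G_A_b37")
  multi <- "1_300_C_T_b37"
  f <- filterVariants(tt, panelKeys, multiallelic = multi)

  ## independent row-by-row rule check
  r <- records(tt)
  oracle <- isBiallelicSnpKey(r$variant_key) &
    !(r$variant_key %in% multi) & (r$variant_key %in% panelKeys)
  expect_identical(records(f)$variant_key, r$variant_key[oracle])
  expect_equal(nrow(records(f)), 2L)
  expect_equal(attr(f, "removed"),
               c(not_biallelic = 1L, multiallelic = 1L, not_in_panel = 1L))

  f2 <- filterVariants(f, panelKeys, multiallelic = multi)
  expect_identical(records(f2), records(f))       # idempotent
})

test_that("top-eQTL extraction takes min p with byte-wise rsid tie-break", {
  tt <- tinyTable("T",
                  gene_id = rep("G1", 2),
                  variant_key = c("1_100_A_G_b37", "1_200_C_T_b37"),
                  rsid = c("rs2", "rs7"),
                  beta = c(0.5, 0.4), pval = c(1e-8, 1e-6))
  top <- extractTopEqtl(list(T = tt))
  expect_identical(topEntries(top)$rsid, "rs2")    # smallest p wins

  tie <- tinyTable("T",
                   gene_id = rep("G1", 2),
                   variant_key = c("1_100_A_G_b37", "1_200_C_T_b37"),
                   rsid = c("rs2", "rs10"),
                   beta = c(0.5, 0.4), pval = c(1e-9, 1e-9))
  top <- extractTopEqtl(list(T = tie))
  expect_identical(topEntries(top)$rsid, "rs10")   # "rs10" < "rs2" byte-wise
})

test_that("top extraction matches an exhaustive scan on a random fixture", {
  set.seed(7)
  n <- 20
  rows <- data.frame(
    gene_id = sample(c("G1", "G2", "G3"), n, replace = TRUE),
    variant_key = sprintf("1_%d_A_G_b37", seq_len(n) * 100),
    rsid = sprintf("rs%d", sample(1000, n)),
    beta = runif(n, 0.1, 1) * sample(c(-1, 1), n, replace = TRUE),
    pval = 10^-sample(4:9, n, replace = TRUE),
    tss_distance = sample(-1e5:1e5, n), stringsAsFactors = FALSE)
  tabs <- list(A = new("TissueTable", tissue = "A", organSystem = "",
                       records = rows[1:10, ]),
               B = new("TissueTable", tissue = "B", organSystem = "",
                       records = rows[11:20, ]))
  top <- extractTopEqtl(tabs)
  e <- topEntries(top)
  for (t in names(tabs)) {
    r <- records(tabs[[t]])
    for (g in unique(r$gene_id)) {
      sub <- r[r$gene_id == g, ]
      best <- sub[sub$pval == min(sub$pval), ]
      want <- sort(best$rsid, method = "radix")[1]  # exhaustive scan oracle
      expect_identical(e$rsid[e$gene_id == g & e$tissue == t], want)
    }
    ## one entry per (gene, tissue) with >= 1 record
    expect_setequal(e$gene_id[e$tissue == t], unique(r$gene_id))
  }
})
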