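## Synthetic multi-tissue eQTL cohort generator with planted ground truth.
## Emits every input the pipeline consumes: a phased haplotype panel (VCF),
## per-tissue significant-pair tables (TSV), an epigenetic annotation matrix
## and a GWAS-catalog table, all as deterministic functions of the config seed.

#' Build a synthetic-cohort configuration
#'
#' See \linkS4class{SimConfig} for the meaning of every knob. Defaults give a
#' desk-scale cohort (200 genes x 6 tissues, 200 haplotypes, 40 LD blocks of
#' 8 SNPs) with a planted opposite-effect fraction of 0.1, strong effects
#' that are always detected at the causal SNP, TSS distances drawn from a
#' uniform cis background plus a Laplace peak at the TSS (sharper and heavier
#' for opposite genes), and moderate annotation/GWAS enrichment of the
#' planted opposite SNPs.
#'
#' @param seed master seed (mandatory integer).
#' @param nTissues,nGenes,nHaplotypes,nBlocks,snpsPerBlock cohort dimensions.
#' @param blockR2Target target within-block r^2.
#' @param thetaOpp planted fraction of opposite-effect genes.
#' @param betaMeanlog,betaSdlog log-normal |beta| parameters.
#' @param sharingGeomProb geometric parameter for the number of active tissues.
#' @param censorSlope,censorMid logistic detection model on scaled |beta|.
#' @param tissueScaleRange per-tissue sample-size scale range.
#' @param causalDropRate per-tissue probability of censoring a causal record.
#' @param partnerMinAbsR minimum |r| for an LD partner to be emitted.
#' @param tssPeakScale,tssPeakScaleOpp Laplace TSS-peak scale (bp).
#' @param tssBackground,tssBackgroundOpp uniform cis-background weight.
#' @param annotationRate,annotationBoost,availabilityRate,nCells annotation model.
#' @param gwasRho,gwasBackgroundN,gwasNonsigN GWAS-catalog model.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed,
                      nTissues = 6L, nGenes = 200L, nHaplotypes = 200L,
                      nBlocks = 120L, snpsPerBlock = 6L, blockR2Target = 0.9,
                      thetaOpp = 0.1, betaMeanlog = log(0.5), betaSdlog = 0.35,
                      sharingGeomProb = 0.35,
                      censorSlope = 8, censorMid = 0.25,
                      tissueScaleRange = c(0.9, 1.6),
                      causalDropRate = 0, partnerMinAbsR = 0.3,
                      tssPeakScale = 20000, tssPeakScaleOpp = 5000,
                      tssBackground = 0.35, tssBackgroundOpp = 0.10,
                      annotationRate = 0.2, annotationBoost = 0.3,
                      availabilityRate = 0.85, nCells = 12L,
                      gwasRho = 0.3, gwasBackgroundN = 20L, gwasNonsigN = 15L) {
  methods::new("SimConfig",
               nTissues = as.integer(nTissues), nGenes = as.integer(nGenes),
               nHaplotypes = as.integer(nHaplotypes), nBlocks = as.integer(nBlocks),
               snpsPerBlock = as.integer(snpsPerBlock), blockR2Target = blockR2Target,
               thetaOpp = thetaOpp, betaMeanlog = betaMeanlog, betaSdlog = betaSdlog,
               sharingGeomProb = sharingGeomProb, censorSlope = censorSlope,
               censorMid = censorMid, tissueScaleRange = tissueScaleRange,
               causalDropRate = causalDropRate, partnerMinAbsR = partnerMinAbsR,
               tssPeakScale = tssPeakScale, tssPeakScaleOpp = tssPeakScaleOpp,
               tssBackground = tssBackground, tssBackgroundOpp = tssBackgroundOpp,
               annotationRate = annotationRate, annotationBoost = annotationBoost,
               availabilityRate = availabilityRate, nCells = as.integer(nCells),
               gwasRho = gwasRho, gwasBackgroundN = as.integer(gwasBackgroundN),
               gwasNonsigN = as.integer(gwasNonsigN), seed = as.integer(seed))
}

## internal: expected pairwise r^2 of two block SNPs that both copy the block
## core indicator (frequency q) with independent flip probability eps.
.expectedBlockR2 <- function(eps, q) {
  p <- q * (1 - eps) + (1 - q) * eps
  e11 <- q * (1 - eps)^2 + (1 - q) * eps^2
  ((e11 - p^2) / (p * (1 - p)))^2
}

## internal: flip probability achieving the target within-block r^2.
.flipRateFor <- function(target, q) {
  if (target >= 1) return(0)
  f <- function(e) .expectedBlockR2(e, q) - target
  if (f(1e-9) < 0) stop("infeasible within-block r^2 target: ", target)
  stats::uniroot(f, c(1e-9, 0.5 - 1e-9), tol = 1e-10)$root
}

## spacing of SNPs within a block and of block start positions (bp); blocks
## are placed far apart so cross-block LD is free of physical linkage.
.SNP_SPACING <- 150L
.BLOCK_SPACING <- 3000000L

#' Simulate a phased block-diagonal haplotype panel
#'
#' Within each LD block all SNPs copy a common core indicator (ancestral
#' pair) with a per-SNP mutation (flip) rate solved to hit the configured
#' within-block r^2 target; across blocks haplotypes are independent and
#' blocks are placed megabases apart. Allele frequencies are constrained to
#' [0.05, 0.95]. Fully deterministic under the config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{HaplotypePanel}; attribute \code{"blocks"} holds the
#'   block index of each variant.
#' @export
simulatePanel <- function(config) {
  nB <- config@nBlocks; m <- config@snpsPerBlock; nH <- config@nHaplotypes
  withSeed(subSeed(config@seed, 101L), {
    nSnp <- nB * m
    H <- matrix(0L, nSnp, nH)
    blocks <- rep(seq_len(nB), each = m)
    for (b in seq_len(nB)) {
      repeat {
        q <- stats::runif(1, 0.3, 0.7)
        z <- stats::rbinom(nH, 1L, q)
        if (mean(z) >= 0.1 && mean(z) <= 0.9) break
      }
      eps <- .flipRateFor(config@blockR2Target, mean(z))
      for (s in seq_len(m)) {
        row <- (b - 1L) * m + s
        for (try in 1:50) {
          flips <- stats::rbinom(nH, 1L, eps)
          x <- as.integer(xor(z, flips))
          f <- mean(x)
          if (f >= 0.05 && f <= 0.95) break
        }
        H[row, ] <- x
      }
    }
    pos <- as.integer(500000L + (blocks - 1L) * .BLOCK_SPACING +
                        (seq_len(nSnp) - (blocks - 1L) * m - 1L) * .SNP_SPACING)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nSnp, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    rsNum <- sample(100000:9999999, nSnp)
    panel <- methods::new("HaplotypePanel",
                          variantKeys = paste("1", pos, ref, alt, "b37", sep = "_"),
                          rsids = paste0("rs", rsNum),
                          chrom = rep("1", nSnp), pos = pos,
                          haplotypes = H, population = "EUR")
    attr(panel, "blocks") <- blocks
    panel
  })
}

## internal: block index per panel variant (attr or recovered from position gaps).
.panelBlocks <- function(panel) {
  b <- attr(panel, "blocks")
  if (!is.null(b)) return(b)
  cumsum(c(1L, diff(panel@pos) > 1e5 | diff(as.integer(factor(panel@chrom))) != 0))
}

#' Simulate per-tissue significant eQTL tables with planted ground truth
#'
#' Every gene picks a causal LD block and causal SNP. Active tissues (a
#' truncated-geometric number) receive effects with the planted sign pattern:
#' concordant genes share one sign everywhere; opposite genes flip the sign
#' in one designated tissue; genes active in a single tissue are labelled
#' single_tissue. LD partners of the causal SNP enter a tissue's significant
#' table with beta attenuated by the signed haplotype correlation r when they
#' pass the logistic detection model; causal records are always emitted
#' unless censored at the configured causalDropRate. Nominal p-values are a
#' deterministic monotone-decreasing map of scaled |beta| within each tissue,
#' so top-SNP extraction is ground-truth-aware. TSS distances follow the
#' uniform-background + Laplace-peak model (sharper for opposite genes).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param panel the \linkS4class{HaplotypePanel} from \code{\link{simulatePanel}}.
#' @param allAssociations also build per-tissue all-tested tables (every block
#'   SNP of every gene, uncensored) for locus views.
#' @return list with \code{tables} (named list of \linkS4class{TissueTable}),
#'   \code{truth} (\linkS4class{GroundTruth}), \code{organSystems} (named
#'   character), and \code{allAssociations} (named list of data.frames or NULL).
#' @export
simulateEqtlTables <- function(config, panel, allAssociations = FALSE) {
  nT <- config@nTissues
  tissues <- sprintf("TIS%02d", seq_len(nT))
  organ <- stats::setNames(rep_len(c("system_A", "system_B", "system_C"), nT), tissues)
  blocks <- .panelBlocks(panel)
  m <- config@snpsPerBlock
  H <- panel@haplotypes
  withSeed(subSeed(config@seed, 202L), {
    tissueScale <- stats::runif(nT, config@tissueScaleRange[1L], config@tissueScaleRange[2L])
    geneIds <- sprintf("G%04d", seq_len(config@nGenes))
    recs <- vector("list", config@nGenes)
    allRecs <- if (allAssociations) vector("list", config@nGenes) else NULL
    truthG <- vector("list", config@nGenes)
    flagged <- character(0)
    for (g in seq_len(config@nGenes)) {
      blk <- sample.int(config@nBlocks, 1L)
      idx <- which(blocks == blk)
      causal <- idx[sample.int(length(idx), 1L)]
      wantOpp <- stats::runif(1) < config@thetaOpp
      nActive <- min(nT, 1L + stats::rgeom(1L, config@sharingGeomProb))
      if (wantOpp) nActive <- max(2L, nActive)
      active <- sample(tissues, nActive)
      label <- if (wantOpp) "opposite" else if (nActive == 1L) "single_tissue" else "concordant"
      baseSign <- sample(c(-1, 1), 1L)
      betaBase <- stats::rlnorm(1L, config@betaMeanlog, config@betaSdlog)
      mult <- stats::setNames(stats::rlnorm(nActive, 0, 0.1), active)
      signs <- stats::setNames(rep(baseSign, nActive), active)
      pairA <- pairB <- NA_character_
      if (label == "opposite") {
        pr <- sample(active, 2L)
        pairA <- pr[1L]; pairB <- pr[2L]
        signs[pairB] <- -baseSign
      }
      ## TSS placement: uniform cis background or Laplace peak at the TSS
      isOpp <- label == "opposite"
      w <- if (isOpp) config@tssBackgroundOpp else config@tssBackground
      sc <- if (isOpp) config@tssPeakScaleOpp else config@tssPeakScale
      span <- (m - 1L) * .SNP_SPACING
      L <- 1e6 - span - 10
      d <- if (stats::runif(1) < w) {
        stats::runif(1, -L, L)
      } else {
        max(-L, min(L, sample(c(-1, 1), 1L) * stats::rexp(1L, 1 / sc)))
      }
      d <- round(d)
      tss <- panel@pos[causal] - d
      dists <- panel@pos[idx] - tss
      ## signed haplotype correlation of every block SNP with the causal SNP
      r <- suppressWarnings(as.numeric(stats::cor(H[causal, ], t(H[idx, , drop = FALSE]))))
      r[is.na(r)] <- 0
      perTissue <- vector("list", nActive)
      allPerTissue <- if (allAssociations) vector("list", nActive) else NULL
      for (ti in seq_along(active)) {
        t <- active[ti]
        tsc <- tissueScale[match(t, tissues)]
        beta <- signs[t] * betaBase * mult[t] * r
        pval <- 10^(-(0.1 + 8 * tsc * abs(beta)))
        isCausal <- idx == causal
        detP <- stats::plogis(config@censorSlope * (tsc * abs(beta) - config@censorMid))
        detected <- stats::runif(length(idx)) < detP
        keep <- (isCausal & stats::runif(length(idx)) >= config@causalDropRate) |
          (!isCausal & abs(r) >= config@partnerMinAbsR & detected)
        if (any(keep)) {
          perTissue[[ti]] <- data.frame(
            tissue = t, gene_id = geneIds[g],
            variant_key = panel@variantKeys[idx][keep],
            rsid = panel@rsids[idx][keep],
            beta = beta[keep], pval = pval[keep],
            tss_distance = dists[keep], stringsAsFactors = FALSE)
        }
        if (allAssociations) {
          allPerTissue[[ti]] <- data.frame(
            tissue = t, gene_id = geneIds[g],
            variant_key = panel@variantKeys[idx],
            rsid = panel@rsids[idx],
            beta = beta, pval = pval,
            tss_distance = dists, stringsAsFactors = FALSE)
        }
      }
      recs[[g]] <- data.table::rbindlist(perTissue[!vapply(perTissue, is.null, TRUE)])
      if (allAssociations) allRecs[[g]] <- data.table::rbindlist(allPerTissue)
      if (isOpp) flagged <- c(flagged, panel@rsids[idx][abs(r) > 0.8])
      truthG[[g]] <- data.frame(
        gene_id = geneIds[g], label = label, tissue_a = pairA, tissue_b = pairB,
        causal_rsid = panel@rsids[causal], causal_key = panel@variantKeys[causal],
        block = blk, tss = tss, n_active = nActive, stringsAsFactors = FALSE)
    }
    all <- data.table::rbindlist(recs)
    tables <- lapply(tissues, function(t) {
      r <- as.data.frame(all[all$tissue == t, -1L])
      methods::new("TissueTable", tissue = t, organSystem = unname(organ[t]),
                   records = r)
    })
    names(tables) <- tissues
    allAssoc <- NULL
    if (allAssociations) {
      aa <- data.table::rbindlist(allRecs)
      allAssoc <- lapply(tissues, function(t) as.data.frame(aa[aa$tissue == t, -1L]))
      names(allAssoc) <- tissues
    }
    flagged <- unique(flagged)
    truth <- methods::new("GroundTruth",
                          genes = do.call(rbind, truthG),
                          snps = data.frame(rsid = panel@rsids,
                                            annotation_flag = panel@rsids %in% flagged,
                                            gwas_partner_flag = panel@rsids %in% flagged,
                                            stringsAsFactors = FALSE))
    list(tables = tables, truth = truth, organSystems = organ,
         allAssociations = allAssoc)
  })
}

#' Simulate an epigenetic annotation matrix
#'
#' Bernoulli presence per (SNP, cell line, mark) at the background rate,
#' boosted (additively, capped at 1) for SNPs flagged in the ground truth;
#' the (cell, mark) availability mask is itself Bernoulli, with the first
#' cell line forced available so every mark has data.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param panel the \linkS4class{HaplotypePanel}.
#' @param truth the \linkS4class{GroundTruth} from \code{\link{simulateEqtlTables}}.
#' @return an \linkS4class{AnnotationMatrix}.
#' @export
simulateAnnotations <- function(config, panel, truth) {
  withSeed(subSeed(config@seed, 303L), {
    snps <- panel@rsids
    cells <- sprintf("CELL%03d", seq_len(config@nCells))
    marks <- .EPI_MARKS
    avail <- matrix(stats::runif(length(cells) * length(marks)) < config@availabilityRate,
                    length(cells), length(marks), dimnames = list(cells, marks))
    avail[1L, ] <- TRUE
    rate <- ifelse(truth@snps$annotation_flag[match(snps, truth@snps$rsid)],
                   pmin(1, config@annotationRate + config@annotationBoost),
                   config@annotationRate)
    pres <- array(FALSE, dim = c(length(snps), length(cells), length(marks)),
                  dimnames = list(snps, cells, marks))
    for (mi in seq_along(marks)) {
      for (ci in seq_along(cells)) {
        if (!avail[ci, mi]) next
        pres[, ci, mi] <- stats::runif(length(snps)) < rate
      }
    }
    methods::new("AnnotationMatrix", presence = pres, availability = avail)
  })
}

#' Simulate a GWAS-catalog association table
#'
#' For every planted opposite gene, with probability gwasRho an LD partner of
#' its causal SNP from the same block with verified r^2 > 0.8 (the causal SNP
#' itself when no other partner qualifies) is emitted as a trait association
#' with p below 5e-8. Background associations are placed on random panel
#' SNPs, and a few rows with p >= 5e-8 are included to exercise the
#' significance filter.
#'
#' @inheritParams simulateAnnotations
#' @return data.frame in the catalog dialect (columns \code{SNPS},
#'   \code{P-VALUE}, \code{DISEASE/TRAIT}).
#' @export
simulateGwasCatalog <- function(config, panel, truth) {
  blocks <- .panelBlocks(panel)
  H <- panel@haplotypes
  withSeed(subSeed(config@seed, 404L), {
    rows <- list()
    oppCausal <- truth@genes$causal_rsid[truth@genes$label == "opposite"]
    k <- 0L
    for (s in oppCausal) {
      if (stats::runif(1) >= config@gwasRho) next
      i <- match(s, panel@rsids)
      mates <- which(blocks == blocks[i])
      r2 <- vapply(mates, function(j) {
        if (j == i) 1 else {
          v <- .r2FromVectors(H[i, ], H[j, ])
          if (is.na(v)) 0 else v
        }
      }, 0)
      cand <- mates[r2 > 0.8]
      partner <- if (length(setdiff(cand, i))) {
        sample(rep(setdiff(cand, i), 2L), 1L)
      } else i
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        SNPS = panel@rsids[partner],
        `P-VALUE` = 10^-stats::runif(1, 8.5, 30),
        `DISEASE/TRAIT` = sprintf("trait_%03d", k),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    bg <- sample(panel@rsids, min(config@gwasBackgroundN, length(panel@rsids)))
    for (s in bg) {
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        SNPS = s, `P-VALUE` = 10^-stats::runif(1, 8.5, 30),
        `DISEASE/TRAIT` = sprintf("trait_%03d", k),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    ns <- sample(panel@rsids, min(config@gwasNonsigN, length(panel@rsids)))
    for (s in ns) {
      k <- k + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        SNPS = s, `P-VALUE` = 10^-stats::runif(1, 2, 7),
        `DISEASE/TRAIT` = sprintf("trait_%03d", k),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    out <- as.data.frame(data.table::rbindlist(rows))
    names(out) <- c("SNPS", "P-VALUE", "DISEASE/TRAIT")
    out
  })
}

#' Simulate a full cohort
#'
#' Convenience wrapper: panel, per-tissue tables, ground truth, annotation
#' matrix and GWAS catalog, all from one config.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param allAssociations also build all-tested association tables.
#' @return named list: panel, tables, truth, organSystems, allAssociations,
#'   annotations, gwas.
#' @export
simulateCohort <- function(config, allAssociations = FALSE) {
  panel <- simulatePanel(config)
  eq <- simulateEqtlTables(config, panel, allAssociations = allAssociations)
  ann <- simulateAnnotations(config, panel, eq$truth)
  gwas <- simulateGwasCatalog(config, panel, eq$truth)
  c(list(panel = panel, annotations = ann, gwas = gwas), eq)
}

#' Write a simulated cohort to disk in the consumed dialects
#'
#' Emits per-tissue significant-pair TSVs, the phased panel VCF, the long
#' annotation TSV, the GWAS-catalog TSV and a ground_truth.json.
#'
#' @param cohort output of \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (t in names(cohort$tables)) {
    p <- file.path(dir, paste0(t, ".signif_pairs.tsv"))
    writeTissueTable(cohort$tables[[t]], p)
    paths[t] <- p
  }
  paths["panel"] <- writePanelVcf(cohort$panel, file.path(dir, "panel.vcf"))
  paths["annotations"] <- writeAnnotationMatrix(cohort$annotations,
                                                file.path(dir, "annotations.tsv"))
  gp <- file.path(dir, "gwas_catalog.tsv")
  data.table::fwrite(cohort$gwas, gp, sep = "\t", quote = FALSE)
  paths["gwas"] <- gp
  tj <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(genes = cohort$truth@genes, snps = cohort$truth@snps),
                       tj, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- tj
  invisible(paths)
}
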