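## Reading, filtering and indexing per-tissue significant cis-eQTL tables.

.EQTL_COLS <- c(gene_id = "gene_id", variant_id = "variant_id",
                rs_id = "rs_id_dbSNP", tss_distance = "tss_distance",
                slope = "slope", pval = "pval_nominal")

#' Load a per-tissue significant variant-gene pair table
#'
#' Reads a tab-separated summary-statistics file (header row, columns
#' \code{gene_id}, \code{variant_id}, \code{rs_id_dbSNP}, \code{tss_distance},
#' \code{slope}, \code{pval_nominal}; optionally gzip-compressed) into a
#' \linkS4class{TissueTable}. Rows whose mandatory fields do not parse — or
#' that violate the record invariants (p-value not in (0, 1], slope exactly 0,
#' |TSS distance| above the 1 Mb cis window, non-biallelic variant key) — are
#' rejected; the rejection count is reported via a message and returned in the
#' \code{"rejected"} attribute.
#'
#' @param path path to the TSV (optionally .gz).
#' @param tissue tissue code for the table.
#' @param organSystem optional organ-system category label.
#' @return a \linkS4class{TissueTable}; attribute \code{"rejected"} carries the
#'   number of rejected rows.
#' @export
loadSignificantPairs <- function(path, tissue, organSystem = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c(1L)), data.table = FALSE)
  missing <- setdiff(unname(.EQTL_COLS), names(raw))
  if (length(missing)) stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) stop("zero data rows in ", path)
  rec <- data.frame(
    gene_id = as.character(raw[["gene_id"]]),
    variant_key = as.character(raw[["variant_id"]]),
    rsid = as.character(raw[["rs_id_dbSNP"]]),
    beta = suppressWarnings(as.numeric(raw[["slope"]])),
    pval = suppressWarnings(as.numeric(raw[["pval_nominal"]])),
    tss_distance = suppressWarnings(as.numeric(raw[["tss_distance"]])),
    stringsAsFactors = FALSE
  )
  bad <- is.na(rec$beta) | is.na(rec$pval) | is.na(rec$tss_distance) |
    is.na(rec$gene_id) | !nzchar(rec$gene_id) | !nzchar(rec$rsid) |
    rec$pval <= 0 | rec$pval > 1 | rec$beta == 0 | abs(rec$tss_distance) > 1e6
  nRejected <- sum(bad)
  rec <- rec[!bad, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no valid rows in ", path)
  if (anyDuplicated(paste(rec$gene_id, rec$variant_key))) {
    stop("duplicated (gene_id, variant_id) pair in ", path)
  }
  if (nRejected > 0L) message(nRejected, " row(s) rejected while loading ", basename(path))
  out <- methods::new("TissueTable", tissue = tissue, organSystem = organSystem,
                      records = rec)
  attr(out, "rejected") <- nRejected
  out
}

#' Write a TissueTable back to the input TSV dialect
#'
#' Inverse of \code{\link{loadSignificantPairs}} up to column order; used for
#' round-tripping and for emitting synthetic cohorts.
#'
#' @param table a \linkS4class{TissueTable}.
#' @param path output path (".gz" suffix triggers gzip).
#' @return the path, invisibly.
#' @export
writeTissueTable <- function(table, path) {
  r <- records(table)
  ## 17 significant digits so numeric fields round-trip bit-exactly
  out <- data.frame(gene_id = r$gene_id, variant_id = r$variant_key,
                    rs_id_dbSNP = r$rsid,
                    tss_distance = sprintf("%.17g", r$tss_distance),
                    slope = sprintf("%.17g", r$beta),
                    pval_nominal = sprintf("%.17g", r$pval))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Filter a tissue table against a reference panel
#'
#' Keeps exactly the records whose variant is a biallelic SNP, is not listed
#' as multi-allelic, and is present in the reference haplotype panel —
#' mirroring the removal of indels, multi-allelic SNPs and variants absent
#' from the reference panel before any LD analysis.
#'
#' @param table a \linkS4class{TissueTable}.
#' @param panelKeys character vector of variant keys present in the panel
#'   (e.g. \code{variantKeys(panel)}).
#' @param multiallelic variant keys to exclude as multi-allelic.
#' @return filtered \linkS4class{TissueTable}; attribute \code{"removed"} is a
#'   named count vector (not_biallelic, multiallelic, not_in_panel).
#' @export
filterVariants <- function(table, panelKeys, multiallelic = character()) {
  r <- records(table)
  biallelic <- isBiallelicSnpKey(r$variant_key)
  multi <- r$variant_key %in% multiallelic
  inPanel <- r$variant_key %in% panelKeys
  keep <- biallelic & !multi & inPanel
  removed <- c(not_biallelic = sum(!biallelic),
               multiallelic = sum(biallelic & multi),
               not_in_panel = sum(biallelic & !multi & !inPanel))
  if (!any(keep)) warning("no records survive filtering for tissue ", tissueCode(table))
  out <- methods::new("TissueTable", tissue = tissueCode(table),
                      organSystem = table@organSystem,
                      records = r[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Extract per-gene per-tissue top eQTL SNPs
#'
#' For every (gene, tissue) with at least one significant record, selects the
#' record with the minimum nominal p-value; among exact p-value ties the
#' lexicographically smallest rsid string wins (plain byte-wise comparison
#' including the "rs" prefix, so "rs10" < "rs2").
#'
#' @param tables list of (filtered) \linkS4class{TissueTable} objects.
#' @return a \linkS4class{TopEqtlMap}.
#' @export
extractTopEqtl <- function(tables) {
  if (methods::is(tables, "TissueTable")) tables <- list(tables)
  pieces <- lapply(tables, function(tt) {
    r <- records(tt)
    if (!nrow(r)) return(NULL)
    cbind(r, tissue = tissueCode(tt), stringsAsFactors = FALSE)
  })
  all <- data.table::rbindlist(pieces)
  if (!nrow(all)) stop("no records in any tissue table")
  ## byte-wise rsid order regardless of locale
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  data.table::setorder(all, gene_id, tissue, pval, rsid)
  top <- all[!duplicated(paste(all$gene_id, all$tissue)), ]
  e <- data.frame(gene_id = top$gene_id, tissue = top$tissue, rsid = top$rsid,
                  variant_key = top$variant_key, beta = top$beta,
                  pval = top$pval, tss_distance = top$tss_distance,
                  stringsAsFactors = FALSE)
  methods::new("TopEqtlMap", entries = e)
}
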