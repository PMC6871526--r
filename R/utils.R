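## Internal helpers shared across modules.

#' @importFrom stats cor sd rbinom runif rlnorm rgeom plogis quantile dnorm
#'   bw.nrd0 fisher.test hclust dist as.dendrogram
NULL

.datatable.aware <- TRUE

## Derive a reproducible sub-seed from a master seed and a counter.
## Kept below 2^31 so it is always a valid R integer seed.
subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647L + 48271 * as.numeric(i)) %% 2147483647L)
}

## Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Parse variant keys of the form chrom_pos_ref_alt_build
#'
#' @param keys character vector of variant keys (e.g. \code{"1_12345_A_G_b37"}).
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{build}; unparseable keys yield NA fields.
#' @export
parseVariantKey <- function(keys) {
  parts <- strsplit(keys, "_", fixed = TRUE)
  ok <- lengths(parts) == 5L
  get_f <- function(i) vapply(parts, function(p) if (length(p) == 5L) p[i] else NA_character_, "")
  data.frame(
    chrom = get_f(1L),
    pos = suppressWarnings(as.integer(get_f(2L))),
    ref = get_f(3L),
    alt = get_f(4L),
    build = get_f(5L),
    stringsAsFactors = FALSE
  )
}

#' Test whether variant keys denote biallelic SNPs
#'
#' A key qualifies when it parses and both ref and alt are single bases in
#' A/C/G/T (indels and malformed keys fail).
#'
#' @param keys character vector of variant keys.
#' @return logical vector.
#' @export
isBiallelicSnpKey <- function(keys) {
  p <- parseVariantKey(keys)
  base <- c("A", "C", "G", "T")
  !is.na(p$pos) & p$ref %in% base & p$alt %in% base
}

#' Pearson (non-excess) sample kurtosis
#'
#' Computes m4 / m2^2 from the central sample moments of the raw values.
#' A normal sample approaches 3; a symmetric two-point sample gives 1.
#'
#' @param x numeric vector, length >= 4, nonzero variance.
#' @return kurtosis (numeric scalar).
#' @export
sampleKurtosis <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L) stop("kurtosis requires at least 4 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("kurtosis undefined for zero-variance sample")
  mean((x - m)^4) / m2^2
}

## Exceedance p-value with strict-bound reporting when no replicate reaches
## the observed value: p < 1/n_rep.
exceedanceP <- function(replicates, observed) {
  n <- length(replicates)
  k <- sum(replicates >= observed)
  list(pvalue = k / n, bound = k == 0L, nRep = n,
       pLabel = if (k == 0L) sprintf("< %g", 1 / n) else sprintf("%g", k / n))
}
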