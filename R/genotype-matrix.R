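#' Construct a genotype matrix
#'
#' The central container of the package: a sites-by-samples table of unphased
#' diploid dosage codes (0 = hom-ref, 1 = het, 2 = hom-alt, -1 = missing)
#' together with per-site metadata (chromosome, 1-based position, ref/alt
#' alleles, alternate-allele frequency).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based integer),
#'   `ref`, `alt` and optionally `alt_af`; positions must be strictly
#'   increasing within each chromosome. An optional `arm` column labels the
#'   analysis unit each site belongs to (defaults to the chromosome).
#' @param calls integer matrix, `nrow(sites)` x `length(samples)`, with codes
#'   in {0, 1, 2, -1}.
#' @param samples character vector of sample identifiers.
#'
#' @details When `alt_af` is absent or `NA`, it is recomputed from the calls
#'   as the alternate-allele frequency over non-missing genotypes.
#'
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(sites, calls, samples) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(sites))
    stop("calls must have one row per site")
  if (ncol(calls) != length(samples))
    stop("calls must have one column per sample")
  bad <- !(calls %in% c(-1L, 0L, 1L, 2L))
  if (any(bad))
    stop("genotype codes must be in {-1, 0, 1, 2}")
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(sites$arm)) sites$arm <- sites$chrom
  if (is.null(sites$alt_af)) sites$alt_af <- NA_real_
  na_af <- is.na(sites$alt_af)
  if (any(na_af))
    sites$alt_af[na_af] <- compute_alt_af(calls[na_af, , drop = FALSE])
  if (any(sites$alt_af < 0 | sites$alt_af > 1, na.rm = TRUE))
    stop("alt_af must lie in [0, 1]")
  dimnames(calls) <- list(NULL, samples)
  structure(list(sites = sites, samples = as.character(samples), calls = calls),
            class = "GenotypeMatrix")
}

## alt-allele frequency from dosage codes, missing (-1) excluded from denominator
compute_alt_af <- function(calls) {
  ok <- calls >= 0L
  num <- rowSums(calls * ok)
  den <- 2 * rowSums(ok)
  ifelse(den > 0, num / den, NA_real_)
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d sites x %d samples on %d chromosome(s)\n",
              nrow(x$sites), length(x$samples), length(unique(x$sites$chrom))))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) c(nrow(x$sites), length(x$samples))

#' Subset a genotype matrix by site index
#'
#' @param gm a `GenotypeMatrix`.
#' @param idx logical or integer site index; integer indices must be
#'   increasing so site order is preserved.
#' @param recompute_af recompute `alt_af` from the retained calls
#'   (default `FALSE`: frequencies travel with the sites).
#' @return A `GenotypeMatrix` with the selected sites.
#' @export
subset_sites <- function(gm, idx, recompute_af = FALSE) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  if (is.logical(idx)) idx <- which(idx)
  if (is.unsorted(idx, strictly = TRUE))
    stop("site index must be strictly increasing")
  sites <- gm$sites[idx, , drop = FALSE]
  rownames(sites) <- NULL
  calls <- gm$calls[idx, , drop = FALSE]
  if (recompute_af) sites$alt_af <- compute_alt_af(calls)
  genotype_matrix(sites, calls, gm$samples)
}
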