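#' Site-filter parameters
#'
#' Mirrors the pre-calling variant filters used for cohort ROH analysis:
#' biallelic SNPs only, allele frequency within `[af_min, af_max]`
#' (inclusive on both ends), and no missing call in any sample.
#'
#' @param af_min,af_max allele-frequency bounds (defaults 0.05 and 0.95).
#' @param require_biallelic_snp drop sites whose ref or alt is not a single
#'   base (default TRUE).
#' @param exclude_missing drop sites with any missing call, cohort-wide
#'   (default TRUE).
#' @param excluded_regions optional interval data.frame (1-based inclusive),
#'   e.g. centromeres, consumed by [split_arms_and_exclude()].
#' @param array_mask optional site mask (data.frame with `chrom`, `pos`),
#'   consumed by [trim_to_mask()].
#' @return A `FilterParams` list.
#' @export
filter_params <- function(af_min = 0.05, af_max = 0.95, require_biallelic_snp = TRUE,
                          exclude_missing = TRUE, excluded_regions = NULL,
                          array_mask = NULL) {
  stopifnot(af_min >= 0, af_min <= af_max, af_max <= 1)
  structure(list(af_min = af_min, af_max = af_max,
                 require_biallelic_snp = require_biallelic_snp,
                 exclude_missing = exclude_missing,
                 excluded_regions = excluded_regions, array_mask = array_mask),
            class = "FilterParams")
}

#' Filter variant sites before ROH calling
#'
#' Rules apply in order: biallelic SNP, allele frequency, missingness. A site
#' with any missing call is dropped for all samples (cohort-wide filter).
#'
#' @param gm a `GenotypeMatrix`.
#' @param params a [filter_params()] object.
#' @return List with `gm` (the retained sites) and `report` (data.frame
#'   `rule`, `sites_removed`, plus a `retained` summary row).
#' @export
filter_sites <- function(gm, params = filter_params()) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  keep <- rep(TRUE, nrow(gm$sites))
  removed <- c(biallelic_snp = 0L, allele_frequency = 0L, missingness = 0L)
  if (params$require_biallelic_snp) {
    ok <- nchar(gm$sites$ref) == 1L & nchar(gm$sites$alt) == 1L &
      gm$sites$ref %in% c("A", "C", "G", "T") & gm$sites$alt %in% c("A", "C", "G", "T")
    removed["biallelic_snp"] <- sum(keep & !ok)
    keep <- keep & ok
  }
  af_ok <- gm$sites$alt_af >= params$af_min & gm$sites$alt_af <= params$af_max
  af_ok[is.na(af_ok)] <- FALSE
  removed["allele_frequency"] <- sum(keep & !af_ok)
  keep <- keep & af_ok
  if (params$exclude_missing) {
    no_miss <- rowSums(gm$calls < 0L) == 0L
    removed["missingness"] <- sum(keep & !no_miss)
    keep <- keep & no_miss
  }
  report <- data.frame(rule = names(removed), sites_removed = unname(removed),
                       stringsAsFactors = FALSE)
  attr(report, "retained") <- sum(keep)
  out <- subset_sites(gm, keep)
  list(gm = out, report = report)
}

#' Partition chromosomes into arm units at excluded regions
#'
#' Drops sites inside the excluded intervals (inclusive bounds) and labels
#' each remaining site with a contiguous analysis unit ("arm"): a new unit
#' starts after every excluded gap. ROH calling operates per arm, so no
#' segment can span a centromere. Chromosomes without an excluded region keep
#' a single unit.
#'
#' @param gm a `GenotypeMatrix`.
#' @param excluded_regions interval data.frame (`chrom`, `start`, `end`,
#'   1-based inclusive), e.g. centromeres; NULL or empty is a no-op.
#' @return A `GenotypeMatrix` whose `sites$arm` labels the analysis units.
#' @export
split_arms_and_exclude <- function(gm, excluded_regions) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  if (is.null(excluded_regions) || nrow(excluded_regions) == 0) return(gm)
  sites <- gm$sites
  drop <- rep(FALSE, nrow(sites))
  unit <- integer(nrow(sites))   # per-site count of excluded regions passed
  for (i in seq_len(nrow(excluded_regions))) {
    ch <- excluded_regions$chrom[i]
    on_ch <- sites$chrom == ch
    if (!any(on_ch)) {
      warning("excluded region on ", ch, " overlaps no sites; ignored")
      next
    }
    inside <- on_ch & sites$pos >= excluded_regions$start[i] & sites$pos <= excluded_regions$end[i]
    drop <- drop | inside
    unit <- unit + as.integer(on_ch & sites$pos > excluded_regions$end[i])
  }
  arm <- paste0(sites$chrom, "_u", unit + 1L)
  out <- gm
  out$sites$arm <- arm
  subset_sites(out, !drop)
}

#' Restrict a genotype matrix to array-mask sites
#'
#' Retains exactly the sites present in the mask (matched on chromosome and
#' position), preserving order — the array-trimming operation used to emulate
#' SNP-array data from WGS genotypes.
#'
#' @param gm a `GenotypeMatrix`.
#' @param array_mask data.frame with columns `chrom`, `pos`.
#' @return A `GenotypeMatrix`.
#' @export
trim_to_mask <- function(gm, array_mask) {
  stopifnot(inherits(gm, "GenotypeMatrix"), all(c("chrom", "pos") %in% names(array_mask)))
  key_gm <- paste(gm$sites$chrom, gm$sites$pos)
  key_mask <- paste(array_mask$chrom, array_mask$pos)
  subset_sites(gm, key_gm %in% key_mask)
}
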