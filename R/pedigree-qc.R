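#' Mendelian consistency of a parent-parent-child genotype triple
#'
#' Vectorized over sites. A triple is `uninformative` when any member is
#' missing; otherwise `inconsistent` iff the child dosage is impossible under
#' biallelic Mendelian transmission: child 0 with a hom-alt parent, child 2
#' with a hom-ref parent, or child 1 with both parents the same homozygote.
#' Symmetric in father/mother.
#'
#' @param father_code,mother_code,child_code integer dosage codes in
#'   {0, 1, 2, -1}.
#' @return Character vector: `"consistent"`, `"inconsistent"` or
#'   `"uninformative"`.
#' @export
trio_check <- function(father_code, mother_code, child_code) {
  f <- as.integer(father_code); m <- as.integer(mother_code); c <- as.integer(child_code)
  if (any(!(c(f, m, c) %in% c(-1L, 0L, 1L, 2L))))
    stop("genotype codes must be in {-1, 0, 1, 2}")
  res <- rep("consistent", length(c))
  bad <- (c == 0L & (f == 2L | m == 2L)) |
         (c == 2L & (f == 0L | m == 0L)) |
         (c == 1L & ((f == 0L & m == 0L) | (f == 2L & m == 2L)))
  res[bad] <- "inconsistent"
  res[f == -1L | m == -1L | c == -1L] <- "uninformative"
  res
}

#' Scan a cohort for Mendelian-error sites
#'
#' Evaluates every parent-parent-child trio of the pedigree at every site
#' (multi-generation families contribute one trio per child with both
#' parents present) and flags sites whose inconsistencies recur: at least
#' `recurrence_min` inconsistent trios, or an inconsistency rate of at least
#' `rate_min` among informative trios (disjunction).
#'
#' @param gm a `GenotypeMatrix` containing the pedigree members.
#' @param ped a `Pedigree`.
#' @param recurrence_min minimal inconsistent-trio count to flag (default 2).
#' @param rate_min minimal inconsistency rate to flag (default 0.05).
#' @return A `MendelReport` data.frame: `chrom`, `pos`, `informative`,
#'   `inconsistent`, `rate`, `flagged`.
#' @export
site_error_scan <- function(gm, ped, recurrence_min = 2, rate_min = 0.05) {
  stopifnot(inherits(gm, "GenotypeMatrix"), inherits(ped, "Pedigree"))
  trios <- pedigree_trios(ped)
  trios <- trios[trios$father %in% gm$samples & trios$mother %in% gm$samples &
                 trios$child %in% gm$samples, , drop = FALSE]
  n_sites <- nrow(gm$sites)
  informative <- integer(n_sites); inconsistent <- integer(n_sites)
  if (!nrow(trios)) {
    warning("pedigree contains no complete genotyped trio")
  } else {
    for (k in seq_len(nrow(trios))) {
      f <- gm$calls[, trios$father[k]]
      m <- gm$calls[, trios$mother[k]]
      c <- gm$calls[, trios$child[k]]
      inf <- f >= 0L & m >= 0L & c >= 0L
      bad <- inf & ((c == 0L & (f == 2L | m == 2L)) |
                    (c == 2L & (f == 0L | m == 0L)) |
                    (c == 1L & ((f == 0L & m == 0L) | (f == 2L & m == 2L))))
      informative <- informative + as.integer(inf)
      inconsistent <- inconsistent + as.integer(bad)
    }
  }
  rate <- ifelse(informative > 0, inconsistent / informative, 0)
  rep <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    informative = informative, inconsistent = inconsistent,
                    rate = rate,
                    flagged = inconsistent >= recurrence_min | (informative > 0 & rate >= rate_min),
                    stringsAsFactors = FALSE)
  class(rep) <- c("MendelReport", "data.frame")
  rep
}

#' Remove Mendelian-flagged sites from a genotype matrix
#'
#' Flagged sites are identified by (chrom, pos), so a report computed on one
#' cohort (e.g. a pedigreed subset) can prune another sharing the site list.
#'
#' @param gm a `GenotypeMatrix`.
#' @param report a `MendelReport` (or any data.frame with `chrom`, `pos`,
#'   `flagged`).
#' @return A `GenotypeMatrix` without the flagged sites.
#' @export
remove_flagged_sites <- function(gm, report) {
  flagged <- report[report$flagged, c("chrom", "pos")]
  if (!nrow(flagged)) return(gm)
  key_gm <- paste(gm$sites$chrom, gm$sites$pos)
  keep <- !(key_gm %in% paste(flagged$chrom, flagged$pos))
  if (!any(keep))
    return(genotype_matrix(gm$sites[0, , drop = FALSE],
                           gm$calls[0, , drop = FALSE], gm$samples))
  subset_sites(gm, keep)
}

#' Write a Mendelian report as TSV
#' @param report a `MendelReport`.
#' @param path output path.
#' @export
write_mendel_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path, sep = "\t")
  invisible(path)
}
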