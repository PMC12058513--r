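#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses an uncompressed VCFv4.x text file with GT genotypes. Diploid GT
#' strings are mapped to dosage codes: `0/0` -> 0, `0/1` or `1/0` -> 1,
#' `1/1` -> 2, `./.` -> -1 (phased separators `|` are accepted). When
#' `INFO/AF` is absent, the alternate-allele frequency is computed from the
#' non-missing calls.
#'
#' @param path file path.
#' @param multiallelic what to do with records whose ALT holds several
#'   alleles: `"skip"` (default) drops them, `"error"` rejects the file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("malformed VCF: no #CHROM header line in ", path)
  hdr <- hdr[1]
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(genotype_matrix(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), alt_af = numeric(0)),
      matrix(integer(0), 0, length(samples)), samples))
  }
  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(fields) != length(cols))
    stop("malformed VCF: inconsistent column count at data line 1")
  chrom <- fields[[1]]; pos <- as.integer(fields[[2]])
  ref <- fields[[4]]; alt <- fields[[5]]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && multiallelic == "error")
    stop("multiallelic record at line ", hdr + which(multi)[1])
  info <- fields[[8]]
  af <- rep(NA_real_, length(body))
  m <- regmatches(info, regexpr("(?:^|;)AF=([0-9.eE+-]+)", info))
  has_af <- lengths(regmatches(info, gregexpr("(?:^|;)AF=", info))) > 0
  af[has_af] <- as.numeric(sub(".*AF=", "", m))
  gt_col <- fields[10:length(cols)]
  n <- length(body)
  calls <- matrix(NA_integer_, n, length(samples))
  code_of <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = -1L,
               "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L, ".|." = -1L,
               "." = -1L)
  for (j in seq_along(samples)) {
    gt <- sub(":.*", "", gt_col[[j]])
    v <- code_of[gt]
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("unsupported or non-diploid GT '", gt[bad], "' at line ", hdr + bad)
    }
    calls[, j] <- unname(v)
  }
  keep <- !multi
  sites <- data.frame(chrom = chrom[keep], pos = pos[keep], ref = ref[keep],
                      alt = alt[keep], alt_af = af[keep], stringsAsFactors = FALSE)
  genotype_matrix(sites, calls[keep, , drop = FALSE], samples)
}

#' Write a genotype matrix as VCFv4.2
#'
#' Emits a GT-only VCF with contig declarations; round-trips exactly through
#' [read_vcf()].
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output path.
#' @param contig_lengths optional named vector of contig lengths for the
#'   header; defaults to the maximum site position per chromosome.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  chroms <- unique(gm$sites$chrom)
  if (is.null(contig_lengths))
    contig_lengths <- vapply(chroms, function(ch) max(gm$sites$pos[gm$sites$chrom == ch]),
                             numeric(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rohprofiler",
           sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(contig_lengths[chroms])),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
                   gm$samples), collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$calls), ncol(gm$calls))
  nz <- gm$calls >= 0L
  gt[nz] <- gt_str[gm$calls[nz] + 1L]
  body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt, ".", "PASS",
                sprintf("AF=%.6g", gm$sites$alt_af), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, if (nrow(gm$sites)) body), path)
  invisible(path)
}
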