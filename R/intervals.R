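#' Read genomic intervals from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive) are
#' unified into the package's internal convention: 1-based inclusive
#' coordinates. For GFF3, records of type `gene` are kept (all records if no
#' `gene` type is present) and the gene name is taken from the `Name`,
#' `gene_name` or `ID` attribute, in that order.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`
#'   (1-based inclusive), sorted by chromosome and start.
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0)))
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    types <- as.character(gr$type)
    if ("gene" %in% types) gr <- gr[types == "gene"]
    nm <- rep(NA_character_, length(gr))
    for (attr in c("Name", "gene_name", "ID")) {
      if (!is.null(S4Vectors::mcols(gr)[[attr]])) {
        v <- as.character(S4Vectors::mcols(gr)[[attr]])
        nm[is.na(nm) & !is.na(v)] <- v[is.na(nm) & !is.na(v)]
      }
    }
  } else {
    nm <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
                   name = nm, stringsAsFactors = FALSE)
  if (any(df$end < df$start)) stop("interval with end < start in ", path)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write intervals as BED
#'
#' Internal 1-based inclusive intervals are converted to the BED 0-based
#' half-open convention at this boundary.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name` (and `score`).
#' @param path output path.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  out <- data.frame(chrom = intervals$chrom,
                    start = as.integer(intervals$start) - 1L,
                    end = as.integer(intervals$end))
  if (!is.null(intervals$name)) out$name <- intervals$name
  if (!is.null(intervals$score)) {
    if (is.null(out$name)) out$name <- "."
    out$score <- intervals$score
  }
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## internal: intervals data.frame -> GRanges (1-based inclusive on both sides)
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}
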