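#' Per-site cross-individual ROH overlap counts
#'
#' For every analyzed site, the number of distinct individuals whose call set
#' covers that position (an individual with several overlapping segments
#' still counts once).
#'
#' @param calls an `ROHCallSet`.
#' @param sites data.frame with `chrom`, `pos` — the analyzed loci (typically
#'   the filtered genotype-matrix sites).
#' @return data.frame: `chrom`, `pos`, `count`.
#' @export
overlap_track <- function(calls, sites) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  count <- integer(nrow(sites))
  if (nrow(calls)) {
    for (ch in unique(calls$chrom)) {
      on_ch <- which(sites$chrom == ch)
      if (!length(on_ch)) next
      pos <- sites$pos[on_ch]
      segs <- calls[calls$chrom == ch, , drop = FALSE]
      ## per-individual segments are non-overlapping, so incrementing each
      ## segment's covered site range counts individuals, not segments
      delta <- integer(length(pos) + 1L)
      from <- findInterval(segs$start - 1L, pos) + 1L   # first site >= start
      to <- findInterval(segs$end, pos)                 # last site <= end
      ok <- from <= to
      for (k in which(ok)) {
        delta[from[k]] <- delta[from[k]] + 1L
        delta[to[k] + 1L] <- delta[to[k] + 1L] - 1L
      }
      count[on_ch] <- cumsum(delta[seq_along(pos)])
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, count = count,
             stringsAsFactors = FALSE)
}

#' Call ROH islands from an overlap track
#'
#' The threshold is the nearest-rank percentile of the per-site count
#' distribution over all analyzed sites (zero-count sites included — they are
#' analyzed loci). A site qualifies iff its count reaches the threshold and
#' is nonzero; qualifying sites that are adjacent in the analyzed site list
#' (or within `max_merge_gap_bp`) merge into island intervals.
#'
#' @param track output of [overlap_track()].
#' @param percentile percentile in (0, 100); 99.9 and 99.5 are the
#'   conventional choices (top 0.1% / 0.5% of loci).
#' @param max_merge_gap_bp additionally bridge bp gaps up to this size
#'   between qualifying sites (default 0: merge only runs uninterrupted by a
#'   non-qualifying analyzed site).
#' @param include_zero include zero-count sites in the percentile
#'   distribution (default TRUE); FALSE restricts it to covered sites.
#' @return data.frame of islands: `chrom`, `start`, `end`, `n_sites`,
#'   `mean_count`, `max_count`; attribute `threshold` records the count
#'   threshold.
#' @export
call_islands <- function(track, percentile = 99.9, max_merge_gap_bp = 0,
                         include_zero = TRUE) {
  stopifnot(percentile > 0, percentile < 100, nrow(track) >= 1)
  counts <- track$count
  pool <- if (include_zero) counts else counts[counts > 0]
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      n_sites = integer(0), mean_count = numeric(0),
                      max_count = integer(0))
  if (!length(pool) || all(pool == 0)) {
    attr(empty, "threshold") <- 0L
    return(empty)
  }
  srt <- sort(pool)
  thr <- srt[ceiling(percentile / 100 * length(srt))]   # nearest-rank
  qual <- counts >= max(thr, 1L)
  if (!any(qual)) {
    attr(empty, "threshold") <- thr
    return(empty)
  }
  out <- list()
  for (ch in unique(track$chrom[qual])) {
    on_ch <- which(track$chrom == ch)
    q <- which(qual[on_ch])
    pos <- track$pos[on_ch]
    brk <- c(TRUE, diff(q) > 1L & diff(pos[q]) > max_merge_gap_bp)
    for (grp in split(q, cumsum(brk))) {
      cc <- counts[on_ch][grp]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = pos[grp[1]], end = pos[grp[length(grp)]],
        n_sites = length(grp), mean_count = mean(cc), max_count = max(cc),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}

#' Annotate genes overlapping ROH islands
#'
#' A gene is reported for an island iff their intervals overlap by at least
#' 1 bp; genes are deduplicated per island and island order is preserved.
#'
#' @param islands output of [call_islands()].
#' @param gene_intervals data.frame from [read_intervals()] (`chrom`,
#'   `start`, `end`, `name`).
#' @return data.frame: `island_chrom`, `island_start`, `island_end`, `gene`,
#'   `overlap_bp`.
#' @export
annotate_genes <- function(islands, gene_intervals) {
  empty <- data.frame(island_chrom = character(0), island_start = integer(0),
                      island_end = integer(0), gene = character(0),
                      overlap_bp = integer(0))
  if (!nrow(islands) || !nrow(gene_intervals)) return(empty)
  isl <- intervals_to_granges(islands)
  genes <- intervals_to_granges(gene_intervals)
  hits <- GenomicRanges::findOverlaps(isl, genes, minoverlap = 1L)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(isl)[qi],
                                           IRanges::ranges(genes)[si]))
  out <- data.frame(island_chrom = islands$chrom[qi],
                    island_start = islands$start[qi],
                    island_end = islands$end[qi],
                    gene = gene_intervals$name[si],
                    overlap_bp = ov, stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("island_chrom", "island_start", "gene")]), , drop = FALSE]
  out <- out[order(match(paste(out$island_chrom, out$island_start),
                         paste(islands$chrom, islands$start))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an overlap track as bedGraph
#' @param track output of [overlap_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  data.table::fwrite(data.frame(track$chrom, track$pos - 1L, track$pos, track$count),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}
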