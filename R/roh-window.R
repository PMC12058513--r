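#' Sliding-window scanner parameters
#'
#' PLINK-style ROH detection: a fixed-size window of consecutive SNPs slides
#' along each arm; a window is "homozygous" when it contains at most
#' `window_het` heterozygous and `window_missing` missing calls; each SNP is
#' scored by the proportion of windows containing it that are homozygous, and
#' runs of qualifying SNPs become segments subject to count, length, gap and
#' density conditions.
#'
#' Defaults mirror the canonical scanner defaults for array-density data;
#' every value is a tunable. `window_het` is the heterozygote allowance that
#' absorbs genotyping errors (the `Het_1`..`Het_4` sweep varies it). At
#' marker densities far from ~1 SNP/4 kb, scale `window_snp` and `min_snp`
#' so the window span stays below the minimal segment length sought.
#'
#' @param window_snp SNPs per window (default 50).
#' @param window_het heterozygotes allowed per window (default 1).
#' @param window_missing missing calls allowed per window (default 5).
#' @param hit_threshold minimum proportion of homozygous windows for a SNP to
#'   be ROH-eligible (default 0.05, inclusive).
#' @param min_snp minimum SNPs per segment (default 100; use ~25 for the
#'   100 Kb minimal-length class at array density).
#' @param min_length_kb minimal segment length in kb (100/300/1500 per
#'   analysis class; default 100).
#' @param max_gap_kb maximal inter-SNP gap inside a segment (default 1000).
#' @param density_kb_per_snp maximal kb per SNP in a segment (default 50).
#' @return A `WindowParams` list.
#' @export
window_params <- function(window_snp = 50, window_het = 1, window_missing = 5,
                          hit_threshold = 0.05, min_snp = 100, min_length_kb = 100,
                          max_gap_kb = 1000, density_kb_per_snp = 50) {
  stopifnot(window_snp >= 1, window_het >= 0, window_missing >= 0,
            hit_threshold > 0, hit_threshold <= 1, min_snp >= 1)
  structure(list(window_snp = as.integer(window_snp), window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 hit_threshold = hit_threshold, min_snp = as.integer(min_snp),
                 min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
                 density_kb_per_snp = density_kb_per_snp),
            class = "WindowParams")
}

#' Per-SNP homozygous-window hit proportions
#'
#' Rolling O(n) computation. An arm with fewer SNPs than `window_snp` is
#' scored over the single window spanning all its SNPs.
#'
#' @param genotypes integer codes in {0, 1, 2, -1} for one sample, one arm.
#' @param params a [window_params()] object.
#' @return Numeric vector: for each SNP, homozygous windows containing it
#'   divided by windows containing it.
#' @export
window_scan <- function(genotypes, params = window_params()) {
  n <- length(genotypes)
  w <- min(params$window_snp, n)
  het <- as.integer(genotypes == 1L)
  mis <- as.integer(genotypes == -1L)
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis))
  nw <- n - w + 1L                       # windows, indexed by start SNP
  starts <- seq_len(nw)
  ok <- (ch[starts + w] - ch[starts]) <= params$window_het &
        (cm[starts + w] - cm[starts]) <= params$window_missing
  cok <- c(0L, cumsum(as.integer(ok)))
  ## windows containing SNP i start in [max(1, i-w+1), min(i, nw)]
  lo <- pmax(1L, seq_len(n) - w + 1L)
  hi <- pmin(seq_len(n), nw)
  (cok[hi + 1L] - cok[lo]) / (hi - lo + 1L)
}

#' Segment calling from hit proportions
#'
#' SNPs with hit proportion >= `hit_threshold` are ROH-eligible; maximal runs
#' of eligible SNPs are split at inter-SNP gaps above `max_gap_kb`, and a run
#' is kept iff it has at least `min_snp` SNPs, spans at least
#' `min_length_kb`, and its kb-per-SNP density does not exceed
#' `density_kb_per_snp`. Coordinates are the outermost site positions.
#'
#' @param hit_proportions output of [window_scan()].
#' @param genotypes the same sample's genotype codes (for the het count).
#' @param pos site positions (bp).
#' @param params a [window_params()] object.
#' @param sample,chrom,arm segment annotations.
#' @return data.frame of segments (possibly empty) with the `ROHCallSet`
#'   columns plus `n_het`.
#' @export
call_segments <- function(hit_proportions, genotypes, pos, params = window_params(),
                          sample = "S", chrom = "chr", arm = chrom) {
  eligible <- hit_proportions >= params$hit_threshold
  if (!any(eligible)) return(empty_window_segments())
  idx <- which(eligible)
  ## break runs at non-consecutive indices or large bp gaps
  brk <- c(TRUE, diff(idx) > 1L | diff(pos[idx]) > params$max_gap_kb * 1000)
  run_id <- cumsum(brk)
  segs <- lapply(split(idx, run_id), function(ii) {
    len <- pos[ii[length(ii)]] - pos[ii[1]] + 1
    ns <- length(ii)
    if (ns < params$min_snp) return(NULL)
    if (len < params$min_length_kb * 1000) return(NULL)
    if (len / 1000 / ns > params$density_kb_per_snp) return(NULL)
    data.frame(sample = sample, chrom = chrom, arm = arm,
               start = pos[ii[1]], end = pos[ii[length(ii)]],
               length = len, n_sites = ns, caller = "window", score = NA_real_,
               n_het = sum(genotypes[ii] == 1L), stringsAsFactors = FALSE)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) return(empty_window_segments())
  do.call(rbind, segs)
}

empty_window_segments <- function() {
  data.frame(sample = character(0), chrom = character(0), arm = character(0),
             start = integer(0), end = integer(0), length = numeric(0),
             n_sites = integer(0), caller = character(0), score = numeric(0),
             n_het = integer(0))
}

#' Call ROH with the sliding-window scanner
#'
#' @param gm a `GenotypeMatrix` (arm units honored; missing calls allowed up
#'   to `window_missing` per window).
#' @param params a [window_params()] object.
#' @return An `ROHCallSet` data.frame (with an extra `n_het` column).
#' @export
call_roh_window <- function(gm, params = window_params()) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  out <- list()
  for (arm in unique(gm$sites$arm)) {
    sel <- which(gm$sites$arm == arm)
    pos <- gm$sites$pos[sel]
    chrom <- gm$sites$chrom[sel][1]
    for (j in seq_along(gm$samples)) {
      g <- gm$calls[sel, j]
      hits <- window_scan(g, params)
      seg <- call_segments(hits, g, pos, params, sample = gm$samples[j],
                           chrom = chrom, arm = arm)
      if (nrow(seg)) out[[length(out) + 1]] <- seg
    }
  }
  cs <- finish_callset(lapply(out, function(s) s[setdiff(names(s), "n_het")]),
                       gm$samples)
  if (length(out)) {
    nh <- do.call(rbind, out)
    key_cs <- paste(cs$sample, cs$chrom, cs$start)
    cs$n_het <- nh$n_het[match(key_cs, paste(nh$sample, nh$chrom, nh$start))]
  } else {
    cs$n_het <- integer(0)
  }
  cs
}

#' Heterozygote-allowance sweep
#'
#' Re-runs the window caller across `window_het` values with everything else
#' fixed, and summarizes per-individual mean NROH and SROH per minimal-length
#' class — the instrument used to gauge how genotyping errors break long ROH
#' and how far an allowance recovers them.
#'
#' @param gm a `GenotypeMatrix`.
#' @param params base [window_params()].
#' @param H_values heterozygote allowances to sweep (default 1:4).
#' @param classes minimal-length thresholds in bp
#'   (default `c(1e5, 3e5, 1.5e6)`).
#' @return data.frame: `window_het`, `class_bp`, `mean_nroh`, `mean_sroh`.
#' @export
het_sweep <- function(gm, params = window_params(), H_values = 1:4,
                      classes = c(1e5, 3e5, 1.5e6)) {
  rows <- list()
  for (H in H_values) {
    p <- params; p$window_het <- as.integer(H)
    calls <- call_roh_window(gm, p)
    for (cl in classes) {
      ns <- nroh_sroh(calls, cl, samples = gm$samples)
      rows[[length(rows) + 1]] <- data.frame(
        window_het = H, class_bp = cl,
        mean_nroh = mean(ns$nroh), mean_sroh = mean(ns$sroh))
    }
  }
  do.call(rbind, rows)
}
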