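#' Per-individual NROH and SROH
#'
#' Count and cumulative length (bp) of each individual's ROH segments at or
#' above a minimal-length threshold. Individuals without qualifying segments
#' report (0, 0).
#'
#' @param calls an `ROHCallSet`.
#' @param min_length_bp minimal segment length (bp), inclusive.
#' @param samples optional character vector fixing the individuals reported
#'   (defaults to the call set's cohort when recorded, else the samples
#'   present in `calls`).
#' @return data.frame: `sample`, `nroh`, `sroh`.
#' @export
nroh_sroh <- function(calls, min_length_bp, samples = NULL) {
  if (is.null(samples)) samples <- attr(calls, "samples")
  if (is.null(samples)) samples <- unique(calls$sample)
  keep <- calls$length >= min_length_bp
  nroh <- tabulate(match(calls$sample[keep], samples), nbins = length(samples))
  sroh <- vapply(seq_along(samples), function(j)
    sum(calls$length[keep & calls$sample == samples[j]]), numeric(1))
  data.frame(sample = samples, nroh = nroh, sroh = sroh, stringsAsFactors = FALSE)
}

#' Genomic inbreeding coefficient F_ROH
#'
#' SROH at the chosen minimal length divided by the total autosomal length
#' analyzed.
#'
#' @param calls an `ROHCallSet`.
#' @param min_length_bp minimal segment length (bp).
#' @param autosome_length_bp total autosomal length (bp). For synthetic
#'   cohorts the self-consistent choice is the summed analyzed arm lengths;
#'   for comparability with published values use the full autosomal genome
#'   length.
#' @param samples see [nroh_sroh()].
#' @return data.frame: `sample`, `sroh`, `f_roh`.
#' @export
f_roh <- function(calls, min_length_bp, autosome_length_bp, samples = NULL) {
  if (autosome_length_bp <= 0) stop("autosome_length_bp must be positive")
  ns <- nroh_sroh(calls, min_length_bp, samples)
  data.frame(sample = ns$sample, sroh = ns$sroh,
             f_roh = ns$sroh / autosome_length_bp, stringsAsFactors = FALSE)
}

#' Segment counts per length bin
#'
#' Bins are half-open `[lo, hi)`; the last bin is open-ended. Segments
#' shorter than the first edge fall into an explicit `underflow` bucket, so
#' the total count is conserved.
#'
#' @param calls an `ROHCallSet`.
#' @param bin_edges strictly increasing numeric vector of bp edges, e.g.
#'   `c(1e5, 2e5, 5e5, 1e6, 1.5e6)`.
#' @return data.frame: `bin` (label), `lo`, `hi` (NA for the open end),
#'   `count`.
#' @export
length_bins <- function(calls, bin_edges) {
  stopifnot(length(bin_edges) >= 1, !is.unsorted(bin_edges, strictly = TRUE))
  ## findInterval: length < edge1 -> 0 -> underflow bucket; edges half-open [lo, hi)
  idx <- findInterval(calls$length, bin_edges) + 1L
  n_bins <- length(bin_edges) + 1L      # underflow + one per edge (last open)
  counts <- tabulate(idx, nbins = n_bins)
  lo <- c(NA, bin_edges)
  hi <- c(bin_edges[1], bin_edges[-1], NA)[seq_len(n_bins)]
  labels <- c("underflow",
              paste0("[", format(bin_edges, scientific = FALSE, trim = TRUE), ",",
                     c(format(bin_edges[-1], scientific = FALSE, trim = TRUE), "Inf"),
                     ")"))
  data.frame(bin = labels, lo = lo, hi = hi, count = counts, stringsAsFactors = FALSE)
}

#' Full per-individual and cohort ROH profile
#'
#' @param calls an `ROHCallSet`.
#' @param classes minimal-length thresholds in bp
#'   (default `c(1e5, 3e5, 1.5e6)`, the 100 Kb / 300 Kb / 1.5 Mb classes).
#' @param autosome_length_bp total analyzed autosomal length for F_ROH.
#' @param f_roh_class which class F_ROH uses (default 1.5 Mb).
#' @param samples see [nroh_sroh()].
#' @return List with `per_individual` (sample x class NROH/SROH plus F_ROH),
#'   `cohort` (per class mean NROH/SROH) and `bins`
#'   (default bins 100-200 Kb, 200-500 Kb, 500 Kb-1 Mb, 1-1.5 Mb, >=1.5 Mb).
#' @export
roh_profile <- function(calls, classes = c(1e5, 3e5, 1.5e6), autosome_length_bp,
                        f_roh_class = 1.5e6, samples = NULL) {
  per <- do.call(rbind, lapply(classes, function(cl) {
    ns <- nroh_sroh(calls, cl, samples)
    ns$class_bp <- cl
    ns
  }))
  fr <- f_roh(calls, f_roh_class, autosome_length_bp, samples)
  per$f_roh <- fr$f_roh[match(per$sample, fr$sample)]
  per$f_roh[per$class_bp != f_roh_class] <- NA_real_
  cohort <- do.call(rbind, lapply(classes, function(cl) {
    ns <- per[per$class_bp == cl, ]
    data.frame(class_bp = cl, mean_nroh = mean(ns$nroh), mean_sroh = mean(ns$sroh))
  }))
  bins <- length_bins(calls, c(1e5, 2e5, 5e5, 1e6, 1.5e6))
  list(per_individual = per, cohort = cohort, bins = bins)
}
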