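#' Autozygosity-HMM parameters
#'
#' Two hidden states: `HW` (non-autozygous, Hardy-Weinberg genotype
#' proportions) and `AZ` (autozygous, allele-frequency proportions with
#' heterozygotes arising only through genotyping error). Transitions follow
#' an exponential kernel in genetic distance; emissions convolve the
#' state-conditional genotype priors with a symmetric observation-error
#' channel.
#'
#' @param gt_error_phred phred-scaled genotype error; default 30, i.e. error
#'   probability \eqn{10^{-30/10} = 10^{-3}}, the value used to absorb
#'   spurious heterozygote calls in high-coverage WGS.
#' @param hw_to_az per-bp intensity of entering the autozygous state
#'   (default 6.7e-8).
#' @param az_to_hw per-bp intensity of leaving it (default 5e-9).
#' @param fallback_rec_rate cM/Mb assumed when no genetic map is supplied
#'   (default 1); with a map, physical gaps are rescaled so that a region
#'   recombining faster than this rate behaves as if physically longer.
#' @param viterbi decode with Viterbi (default TRUE); FALSE selects
#'   max-posterior (forward-backward) decoding for diagnostics.
#' @return An `HmmParams` list.
#' @export
hmm_params <- function(gt_error_phred = 30, hw_to_az = 6.7e-8, az_to_hw = 5e-9,
                       fallback_rec_rate = 1, viterbi = TRUE) {
  stopifnot(gt_error_phred >= 0, hw_to_az > 0, az_to_hw > 0, fallback_rec_rate > 0)
  structure(list(gt_error_phred = gt_error_phred, hw_to_az = hw_to_az,
                 az_to_hw = az_to_hw, fallback_rec_rate = fallback_rec_rate,
                 viterbi = viterbi),
            class = "HmmParams")
}

#' Emission probabilities of the autozygosity HMM
#'
#' True-genotype priors are HW: \eqn{(1-f)^2, 2f(1-f), f^2} and AZ:
#' \eqn{(1-f), 0, f}; the observed genotype passes through a symmetric error
#' channel that keeps the true code with probability \eqn{1-e} and emits each
#' of the two wrong codes with probability \eqn{e/2}, where
#' \eqn{e = 10^{-\mathrm{phred}/10}}.
#'
#' @param genotype_code integer vector of observed codes in {0, 1, 2}.
#' @param alt_af alternate-allele frequency (vector, strictly inside (0, 1)).
#' @param gt_error error probability `e` (not phred; see [hmm_params()]).
#' @return Matrix with columns `HW` and `AZ`: P(observed | state).
#' @export
emission_probs <- function(genotype_code, alt_af, gt_error) {
  if (any(genotype_code < 0 | genotype_code > 2))
    stop("genotype codes must be in {0, 1, 2} (filter missing calls first)")
  if (any(alt_af <= 0 | alt_af >= 1))
    stop("monomorphic site (alt_af in {0,1}); apply the AF filter first")
  f <- alt_af
  e <- gt_error
  prior_hw <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  prior_az <- cbind(1 - f, 0, f)
  ## channel matrix C[true+1, obs+1]
  C <- matrix(e / 2, 3, 3); diag(C) <- 1 - e
  obs1 <- cbind(seq_along(genotype_code), genotype_code + 1L)
  hw <- (prior_hw %*% C)[obs1]
  az <- (prior_az %*% C)[obs1]
  cbind(HW = hw, AZ = az)
}

#' Transition matrix of the autozygosity HMM
#'
#' The effective distance between two consecutive sites is the genetic-map
#' gap converted back to bp at the fallback rate (`cM gap / rate * 1e6`);
#' with no map the physical distance is used. Switch probabilities follow
#' the exponential kernel `P = 1 - exp(-intensity * d)`.
#'
#' @param pos_i,pos_j physical positions (bp), `pos_j > pos_i`, same arm.
#' @param map optional `GeneticMap`.
#' @param params an [hmm_params()] object.
#' @param chrom chromosome (required when `map` is given).
#' @return 2x2 matrix, rows = from-state (HW, AZ), rows summing to 1.
#' @export
transition_probs <- function(pos_i, pos_j, map = NULL, params = hmm_params(),
                             chrom = NULL) {
  if (pos_j <= pos_i) stop("pos_j must exceed pos_i")
  d <- effective_distance(pos_i, pos_j, map, params, chrom)
  a <- 1 - exp(-params$hw_to_az * d)
  b <- 1 - exp(-params$az_to_hw * d)
  matrix(c(1 - a, a, b, 1 - b), 2, 2, byrow = TRUE,
         dimnames = list(c("HW", "AZ"), c("HW", "AZ")))
}

## vectorized bp-equivalent distance between consecutive positions
effective_distance <- function(pos_i, pos_j, map = NULL, params, chrom = NULL) {
  if (is.null(map)) return(pos_j - pos_i)
  cm <- interpolate_cM(map, chrom, c(pos_i, pos_j))
  n <- length(pos_i)
  d <- (cm[(n + 1):(2 * n)] - cm[seq_len(n)]) / params$fallback_rec_rate * 1e6
  pmax(d, .Machine$double.xmin)  # flat map stretches: keep transitions proper
}

## core DP over a genotype MATRIX (sites x samples) sharing positions/AFs.
## Returns integer matrix of states (0 = HW, 1 = AZ).
viterbi_matrix <- function(calls, alt_af, pos, map = NULL, chrom = NULL,
                           params = hmm_params()) {
  n <- nrow(calls); m <- ncol(calls)
  e <- 10^(-params$gt_error_phred / 10)
  pi_az <- params$hw_to_az / (params$hw_to_az + params$az_to_hw)
  ## per-gap log transition terms (shared across samples)
  if (n > 1) {
    d <- effective_distance(pos[-n], pos[-1], map, params, chrom)
    a <- 1 - exp(-params$hw_to_az * d)   # HW -> AZ
    b <- 1 - exp(-params$az_to_hw * d)   # AZ -> HW
    l_hh <- log1p(-a); l_ha <- log(a); l_ah <- log(b); l_aa <- log1p(-b)
  }
  ## emissions: 3 possible codes x 2 states, per site; index by observed code
  f <- alt_af
  C <- matrix(e / 2, 3, 3); diag(C) <- 1 - e
  ehw <- log(cbind((1 - f)^2, 2 * f * (1 - f), f^2) %*% C)   # n x 3 (obs code)
  eaz <- log(cbind(1 - f, 0, f) %*% C)
  if (any(calls < 0L)) stop("missing genotypes must be filtered before HMM calling")
  idx1 <- calls[1, ] + 1L
  d_hw <- log1p(-pi_az) + ehw[cbind(1L, idx1)]
  d_az <- log(pi_az) + eaz[cbind(1L, idx1)]
  bp_az <- matrix(FALSE, n, m)  # TRUE: best predecessor of AZ was AZ
  bp_hw <- matrix(FALSE, n, m)  # TRUE: best predecessor of HW was HW
  if (n > 1) for (i in 2:n) {
    g <- i - 1L
    from_hw_to_hw <- d_hw + l_hh[g]
    from_az_to_hw <- d_az + l_ah[g]
    from_hw_to_az <- d_hw + l_ha[g]
    from_az_to_az <- d_az + l_aa[g]
    stay_hw <- from_hw_to_hw >= from_az_to_hw
    stay_az <- from_az_to_az >= from_hw_to_az
    idx <- calls[i, ] + 1L
    d_hw <- pmax(from_hw_to_hw, from_az_to_hw) + ehw[cbind(i, idx)]
    d_az <- pmax(from_az_to_az, from_hw_to_az) + eaz[cbind(i, idx)]
    bp_hw[i, ] <- stay_hw
    bp_az[i, ] <- stay_az
  }
  states <- matrix(0L, n, m)
  cur <- as.integer(d_az > d_hw)
  states[n, ] <- cur
  if (n > 1) for (i in n:2) {
    in_az <- cur == 1L
    prev <- integer(m)
    prev[in_az] <- as.integer(bp_az[i, in_az])          # AZ stayed -> prev AZ
    prev[!in_az] <- as.integer(!bp_hw[i, !in_az])       # HW stayed -> prev HW
    cur <- prev
    states[i - 1L, ] <- cur
  }
  states
}

## forward-backward AZ posteriors for one sample (diagnostics / scoring)
posterior_az <- function(genotypes, alt_af, pos, map = NULL, chrom = NULL,
                         params = hmm_params()) {
  n <- length(genotypes)
  e <- 10^(-params$gt_error_phred / 10)
  pi_az <- params$hw_to_az / (params$hw_to_az + params$az_to_hw)
  E <- emission_probs(genotypes, alt_af, e)
  if (n > 1) {
    d <- effective_distance(pos[-n], pos[-1], map, params, chrom)
    a <- 1 - exp(-params$hw_to_az * d)
    b <- 1 - exp(-params$az_to_hw * d)
  }
  fwd <- matrix(0, n, 2)
  fwd[1, ] <- c(1 - pi_az, pi_az) * E[1, ]
  fwd[1, ] <- fwd[1, ] / sum(fwd[1, ])
  if (n > 1) for (i in 2:n) {
    g <- i - 1L
    p <- c(fwd[i - 1, 1] * (1 - a[g]) + fwd[i - 1, 2] * b[g],
           fwd[i - 1, 1] * a[g] + fwd[i - 1, 2] * (1 - b[g])) * E[i, ]
    fwd[i, ] <- p / sum(p)
  }
  bwd <- matrix(1, n, 2)
  if (n > 1) for (i in (n - 1):1) {
    g <- i
    p <- c((1 - a[g]) * E[i + 1, 1] * bwd[i + 1, 1] + a[g] * E[i + 1, 2] * bwd[i + 1, 2],
           b[g] * E[i + 1, 1] * bwd[i + 1, 1] + (1 - b[g]) * E[i + 1, 2] * bwd[i + 1, 2])
    bwd[i, ] <- p / sum(p)
  }
  post <- fwd * bwd
  post[, 2] / rowSums(post)
}

#' Viterbi decoding of one genotype sequence
#'
#' Maximum-probability state path under the two-state autozygosity HMM, in
#' log space, with the stationary distribution of the per-bp intensities as
#' the initial state distribution. With `params$viterbi = FALSE`, the
#' per-site max-posterior path is returned instead.
#'
#' @param genotypes integer codes in {0, 1, 2} for one sample, one arm unit.
#' @param alt_af,pos per-site allele frequencies and positions.
#' @param map optional `GeneticMap`; `chrom` names the chromosome when given.
#' @param params an [hmm_params()] object.
#' @param chrom chromosome name.
#' @return Integer vector of states: 0 = HW, 1 = AZ.
#' @export
viterbi_decode <- function(genotypes, alt_af, pos, map = NULL, chrom = NULL,
                           params = hmm_params()) {
  stopifnot(length(genotypes) >= 1,
            length(alt_af) == length(genotypes), length(pos) == length(genotypes))
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be strictly increasing")
  if (!params$viterbi)
    return(as.integer(posterior_az(genotypes, alt_af, pos, map, chrom, params) > 0.5))
  viterbi_matrix(matrix(as.integer(genotypes), ncol = 1), alt_af, pos, map, chrom,
                 params)[, 1]
}

#' Call ROH with the autozygosity HMM
#'
#' Decodes every sample on every arm unit and reports maximal runs of
#' AZ-labelled sites as segments, with start/end at the outermost site
#' positions.
#'
#' @param gm a filtered `GenotypeMatrix` (no missing calls, AF-filtered).
#' @param map optional `GeneticMap` scaling transitions; without it, physical
#'   distance at `fallback_rec_rate` is assumed.
#' @param params an [hmm_params()] object.
#' @param score also compute each segment's mean posterior AZ probability
#'   (default FALSE; doubles runtime).
#' @return A data.frame of class `ROHCallSet`: `sample`, `chrom`, `arm`,
#'   `start`, `end`, `length`, `n_sites`, `caller`, `score`, sorted by
#'   sample, chromosome, start; non-overlapping per sample-arm.
#' @export
call_roh_hmm <- function(gm, map = NULL, params = hmm_params(), score = FALSE) {
  stopifnot(inherits(gm, "GenotypeMatrix"))
  out <- list()
  for (arm in unique(gm$sites$arm)) {
    sel <- which(gm$sites$arm == arm)
    pos <- gm$sites$pos[sel]
    f <- gm$sites$alt_af[sel]
    chrom <- gm$sites$chrom[sel][1]
    states <- if (params$viterbi) {
      viterbi_matrix(gm$calls[sel, , drop = FALSE], f, pos, map, chrom, params)
    } else {
      vapply(seq_along(gm$samples), function(j)
        as.integer(posterior_az(gm$calls[sel, j], f, pos, map, chrom, params) > 0.5),
        integer(length(sel)))
    }
    if (is.null(dim(states))) states <- matrix(states, ncol = length(gm$samples))
    for (j in seq_along(gm$samples)) {
      runs <- az_runs(states[, j])
      if (!nrow(runs)) next
      seg <- data.frame(sample = gm$samples[j], chrom = chrom, arm = arm,
                        start = pos[runs$from], end = pos[runs$to],
                        n_sites = runs$to - runs$from + 1L,
                        caller = "hmm", score = NA_real_, stringsAsFactors = FALSE)
      if (score) {
        p_az <- posterior_az(gm$calls[sel, j], f, pos, map, chrom, params)
        seg$score <- vapply(seq_len(nrow(runs)), function(k)
          mean(p_az[runs$from[k]:runs$to[k]]), numeric(1))
      }
      out[[length(out) + 1]] <- seg
    }
  }
  finish_callset(out, gm$samples)
}

## maximal runs of 1s in a 0/1 vector
az_runs <- function(states) {
  r <- rle(states)
  to <- cumsum(r$lengths)
  from <- to - r$lengths + 1L
  keep <- r$values == 1L
  data.frame(from = from[keep], to = to[keep])
}

## assemble, order and class a list of segment data.frames
finish_callset <- function(seg_list, samples) {
  if (!length(seg_list)) {
    calls <- data.frame(sample = character(0), chrom = character(0), arm = character(0),
                        start = integer(0), end = integer(0), length = integer(0),
                        n_sites = integer(0), caller = character(0), score = numeric(0))
  } else {
    calls <- do.call(rbind, seg_list)
  }
  calls$length <- as.numeric(calls$end) - as.numeric(calls$start) + 1
  calls <- calls[order(match(calls$sample, samples), calls$chrom, calls$start), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  calls <- calls[c("sample", "chrom", "arm", "start", "end", "length", "n_sites",
                   "caller", "score")]
  class(calls) <- c("ROHCallSet", "data.frame")
  attr(calls, "samples") <- samples
  calls
}

#' Write an ROH call set as a per-region TSV
#' @param calls an `ROHCallSet`.
#' @param path output path.
#' @export
write_callset <- function(calls, path) {
  data.table::fwrite(as.data.frame(calls)[c("sample", "chrom", "start", "end",
                                            "length", "n_sites", "caller", "score")],
                     path, sep = "\t")
  invisible(path)
}
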