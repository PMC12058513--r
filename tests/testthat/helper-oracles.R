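# Independent oracles, deliberately naive: these re-derive expected results
# by brute force and never share code paths with the implementation.

# Exhaustive best-path search over all 2^n state sequences of the two-state
# autozygosity HMM (states 0 = HW, 1 = AZ).
bf_viterbi <- function(genotypes, alt_af, pos, params) {
  n <- length(genotypes)
  e <- 10^(-params$gt_error_phred / 10)
  pi_az <- params$hw_to_az / (params$hw_to_az + params$az_to_hw)
  E <- emission_probs(genotypes, alt_af, e)       # contract under test elsewhere
  lE <- log(E)
  lT <- vector("list", n - 1)
  if (n > 1) for (i in seq_len(n - 1))
    lT[[i]] <- log(transition_probs(pos[i], pos[i + 1], params = params))
  best <- -Inf; best_path <- NULL
  for (code in 0:(2^n - 1)) {
    path <- as.integer(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    lp <- log(ifelse(path[1] == 1, pi_az, 1 - pi_az)) + lE[1, path[1] + 1]
    if (n > 1) for (i in 2:n)
      lp <- lp + lT[[i - 1]][path[i - 1] + 1, path[i] + 1] + lE[i, path[i] + 1]
    if (lp > best) { best <- lp; best_path <- path }
  }
  best_path
}

# Naive per-SNP hit proportions: enumerate every window explicitly.
naive_window_hits <- function(genotypes, w, H, M) {
  n <- length(genotypes)
  w <- min(w, n)
  nw <- n - w + 1
  ok <- logical(nw)
  for (s in seq_len(nw)) {
    win <- genotypes[s:(s + w - 1)]
    ok[s] <- sum(win == 1) <= H && sum(win == -1) <= M
  }
  sapply(seq_len(n), function(i) {
    ws <- which(seq_len(nw) <= i & seq_len(nw) + w - 1 >= i)
    mean(ok[ws])
  })
}

# Gamete-enumeration Mendelian oracle: a child genotype is possible iff some
# transmitted-allele pair from the parents sums to it.
gamete_trio_oracle <- function(f, m, c) {
  if (any(c(f, m, c) == -1)) return("uninformative")
  alleles <- function(g) switch(as.character(g), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  possible <- outer(alleles(f), alleles(m), "+")
  if (c %in% possible) "consistent" else "inconsistent"
}

# Small genotype-matrix builder for toy cases.
make_gm <- function(calls, pos = NULL, chrom = "chr1", af = NULL,
                    samples = NULL, ref = "A", alt = "G") {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(calls)))
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt)
  if (!is.null(af)) sites$alt_af <- af
  genotype_matrix(sites, calls, samples)
}

# bp-level recovery statistics of a call set against planted truth intervals.
recovery_stats <- function(calls, truth) {
  tot <- sum(truth$end - truth$start + 1)
  ov <- 0; fp <- 0
  for (i in seq_len(nrow(calls))) {
    tt <- truth[truth$sample == calls$sample[i] & truth$chrom == calls$chrom[i], ]
    o <- sum(pmax(0, pmin(tt$end, calls$end[i]) - pmax(tt$start, calls$start[i]) + 1))
    ov <- ov + o
    fp <- fp + (calls$length[i] - o)
  }
  c(recall = ov / tot, fp = fp / tot)
}
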