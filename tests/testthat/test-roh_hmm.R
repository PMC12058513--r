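test_that("emission probabilities follow the error-channel model", {
  # error-free: AZ forbids heterozygotes
  E <- emission_probs(1L, 0.5, 0)
  expect_equal(unname(E[1, "HW"]), 0.5)
  expect_equal(unname(E[1, "AZ"]), 0)
  # e = 1e-3: P(het | AZ) = e/2 * (1-f) + e/2 * f = e/2
  E <- emission_probs(1L, 0.5, 1e-3)
  expect_equal(unname(E[1, "AZ"]), 5e-4)
  # channel conservation: sums over observed codes are 1 for both states
  for (f in c(0.1, 0.37, 0.5, 0.9)) {
    for (e in c(0, 1e-3, 0.05)) {
      E <- emission_probs(0:2, rep(f, 3), e)
      expect_equal(unname(colSums(E)), c(1, 1), tolerance = 1e-12)
    }
  }
  expect_error(emission_probs(1L, 1, 1e-3), "monomorphic")
  expect_error(emission_probs(3L, 0.5, 1e-3), "codes")
})

test_that("transition matrix follows the exponential kernel", {
  p <- hmm_params()
  # zero-distance limit (positions must differ; use 1 bp and tiny intensity)
  Tm <- transition_probs(100, 1e7 + 100, params = p)
  expect_equal(unname(Tm["HW", "AZ"]), 1 - exp(-0.67), tolerance = 1e-12)
  expect_equal(unname(rowSums(Tm)), c(1, 1))
  Tm1 <- transition_probs(100, 101, params = p)
  expect_lt(Tm1["HW", "AZ"], 1e-7)   # ~identity at 1 bp
  expect_error(transition_probs(100, 100, params = p), "exceed")
  # genetic map rescaling: doubling cM/Mb doubles effective distance
  map2 <- uniform_genetic_map(c(chr1 = 1e8), rate = 2)
  Tmap <- transition_probs(100, 1e7 + 100, map = map2, params = p, chrom = "chr1")
  expect_equal(unname(Tmap["HW", "AZ"]), 1 - exp(-0.67 * 2), tolerance = 1e-9)
})

test_that("Viterbi decodes the obvious paths", {
  p <- hmm_params()
  pos <- seq(1, by = 1e4, length.out = 200)
  f <- rep(0.5, 200)
  expect_true(all(viterbi_decode(rep(0L, 200), f, pos, params = p) == 1L))
  alt <- rep(c(1L, 0L), 100)
  expect_true(all(viterbi_decode(alt, f, pos, params = p) == 0L))
})

test_that("Viterbi equals exhaustive enumeration on small random instances", {
  set.seed(99)
  p <- hmm_params()
  for (rep_i in 1:40) {
    n <- sample(2:12, 1)
    g <- sample(0:2, n, replace = TRUE)
    f <- runif(n, 0.05, 0.95)
    pos <- sort(sample.int(5e6, n))
    got <- viterbi_decode(g, f, pos, params = p)
    expect_identical(got, bf_viterbi(g, f, pos, p))
  }
})

test_that("matrix and single-sequence Viterbi implementations agree", {
  set.seed(12)
  n <- 300
  g <- matrix(sample(0:2, n * 5, replace = TRUE, prob = c(.4, .2, .4)), n, 5)
  f <- runif(n, 0.05, 0.95)
  pos <- sort(sample.int(5e6, n))
  gm <- make_gm(g, pos = pos, af = f)
  calls <- call_roh_hmm(gm)
  for (j in 1:5) {
    path <- viterbi_decode(g[, j], f, pos, params = hmm_params())
    segs <- calls[calls$sample == gm$samples[j], ]
    runs <- rle(path)
    expect_equal(nrow(segs), sum(runs$values == 1L))
  }
})

test_that("a single spurious heterozygote is absorbed at e=1e-3 but splits at e=0", {
  pos <- seq(1, by = 1e4, length.out = 201)
  f <- rep(0.5, 201)
  g <- rep(0L, 201); g[101] <- 1L
  gm <- make_gm(matrix(g, ncol = 1), pos = pos, af = f)
  absorbed <- call_roh_hmm(gm, params = hmm_params(gt_error_phred = 30))
  expect_equal(nrow(absorbed), 1)       # NOT split
  split <- call_roh_hmm(gm, params = hmm_params(gt_error_phred = Inf))
  expect_equal(nrow(split), 2)          # e = 0 forbids the het inside AZ
})

test_that("segment recovery of a planted 2 Mb segment at 100 sites/Mb", {
  set.seed(5)
  n <- 1000                             # 10 Mb at 100 sites/Mb
  pos <- sort(sample.int(1e7, n))
  f <- rbeta(n, 2, 2); f <- pmin(pmax(f, 0.05), 0.95)
  h1 <- rbinom(n, 1, f); h2 <- rbinom(n, 1, f)
  inside <- pos >= 4e6 & pos <= 6e6 - 1
  h2[inside] <- h1[inside]
  gm <- make_gm(matrix(h1 + h2, ncol = 1), pos = pos, af = f)
  calls <- call_roh_hmm(gm)
  big <- calls[calls$length > 1e6, ]
  expect_equal(nrow(big), 1)
  covered <- min(big$end, 6e6 - 1) - max(big$start, 4e6) + 1
  expect_gte(covered / 2e6, 0.95)
})

test_that("HMM calls are deterministic and invariant to sample order", {
  set.seed(21)
  n <- 400
  g <- matrix(sample(0:2, n * 4, replace = TRUE, prob = c(.45, .1, .45)), n, 4)
  f <- runif(n, 0.05, 0.95)
  pos <- sort(sample.int(4e6, n))
  gm <- make_gm(g, pos = pos, af = f)
  c1 <- call_roh_hmm(gm)
  c2 <- call_roh_hmm(gm)
  expect_identical(c1, c2)
  gm_rev <- genotype_matrix(gm$sites, gm$calls[, 4:1], gm$samples[4:1])
  c3 <- call_roh_hmm(gm_rev)
  key <- function(x) x[order(x$sample, x$start), c("sample", "start", "end", "n_sites")]
  expect_equal(key(as.data.frame(c3)), key(as.data.frame(c1)), ignore_attr = TRUE)
})

test_that("posterior decoding is available and broadly agrees on clear signal", {
  pos <- seq(1, by = 1e4, length.out = 300)
  f <- rep(0.4, 300)
  g <- c(rep(0L, 150), rep(c(1L, 0L, 2L), 50))
  gm <- make_gm(matrix(g, ncol = 1), pos = pos, af = f)
  vit <- call_roh_hmm(gm, params = hmm_params(viterbi = TRUE))
  post <- call_roh_hmm(gm, params = hmm_params(viterbi = FALSE))
  expect_equal(nrow(vit), 1)
  expect_equal(nrow(post), 1)
  expect_lt(abs(vit$start - post$start), 2e5)
  scored <- call_roh_hmm(gm, score = TRUE)
  expect_gt(scored$score[1], 0.9)
})
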