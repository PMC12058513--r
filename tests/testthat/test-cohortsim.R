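test_that("simulate_sites honours density, ordering and the AF law", {
  cfg <- sim_config(seed = 1, chrom_lengths = c(chr1 = 1e7), site_density = 100)
  sites <- simulate_sites(cfg)
  expect_equal(nrow(sites), 1000)
  expect_true(all(diff(sites$pos) > 0))
  # two chromosomes, each internally sorted
  cfg2 <- sim_config(seed = 1, chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                     site_density = 50)
  s2 <- simulate_sites(cfg2)
  expect_setequal(unique(s2$chrom), c("chr1", "chr2"))
  for (ch in c("chr1", "chr2"))
    expect_true(all(diff(s2$pos[s2$chrom == ch]) > 0))
  # Beta(0.5, 0.5) has mean 0.5; 1e5 draws within 3 SE
  cfg3 <- sim_config(seed = 2, chrom_lengths = c(chr1 = 1e9), site_density = 100,
                     af_shape = c(0.5, 0.5))
  s3 <- simulate_sites(cfg3)
  se <- sqrt(0.125) / sqrt(nrow(s3))       # Beta(.5,.5) variance = 1/8
  expect_lt(abs(mean(s3$alt_af) - 0.5), 3 * se)
  expect_error(sim_config(site_density = 0), "site_density")
})

test_that("planted intervals are homozygous inside and match the truth set", {
  cfg <- sim_config(seed = 3, n_founders = 5, chrom_lengths = c(chr1 = 2e7),
                    site_density = 100, n_segments_short = 3, n_segments_long = 1,
                    long_mean_excess_bp = 1e6, het_error_rate = 0)
  sites <- simulate_sites(cfg)
  fo <- simulate_founders(sites, cfg)
  expect_equal(nrow(fo$truth), 5 * 4)
  for (i in seq_len(nrow(fo$truth))) {
    tr <- fo$truth[i, ]
    j <- match(tr$sample, fo$gm$samples)
    inside <- sites$chrom == tr$chrom & sites$pos >= tr$start & sites$pos <= tr$end
    expect_false(any(fo$gm$calls[inside, j] == 1L))
  }
  # per sample-chromosome: non-overlapping, sorted
  for (s in unique(fo$truth$sample)) {
    tt <- fo$truth[fo$truth$sample == s, ]
    expect_true(all(diff(tt$start) > 0))
    expect_true(all(tt$start[-1] > tt$end[-nrow(tt)]))
  }
  expect_error(
    simulate_founders(sites, sim_config(seed = 3, n_founders = 1,
                                        chrom_lengths = c(chr1 = 2e7),
                                        site_density = 100, n_segments_short = 1,
                                        n_segments_long = 0,
                                        short_range_bp = c(3e7, 3e7))),
    "longer than its chromosome")
})

test_that("founder genotypes follow Hardy-Weinberg at fixed frequency", {
  sites <- data.frame(chrom = "chr1", pos = seq_len(10000) * 1000,
                      ref = "A", alt = "G", alt_af = 0.5)
  cfg <- sim_config(seed = 4, n_founders = 2, chrom_lengths = c(chr1 = 1e7 + 1),
                    n_segments_short = 0, n_segments_long = 0, het_error_rate = 0)
  fo <- simulate_founders(sites, cfg)
  het_frac <- mean(fo$gm$calls[, 1] == 1L)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het_frac - 0.5), 3 * se)   # HWE: 2pq = 0.5 at p = 0.5
})

test_that("pedigree transmission is Mendelian and Haldane-distributed", {
  cfg <- sim_config(seed = 5, pedigree_spec = list(trios = 50),
                    chrom_lengths = c(chr1 = 1e8), site_density = 10,
                    n_segments_short = 0, n_segments_long = 0, het_error_rate = 0,
                    rec_rate_cM_per_Mb = 1)
  sites <- simulate_sites(cfg)
  ped <- make_pedigree(trios = 50)
  fnd <- pedigree_founders(ped)
  cfg2 <- cfg; cfg2$n_founders <- length(fnd)
  fo <- simulate_founders(sites, cfg2, founder_ids = fnd)
  map <- uniform_genetic_map(cfg$chrom_lengths, 1)
  tr <- transmit_pedigree(fo, ped, map, cfg)
  # both parents hom-ref at a site -> child hom-ref
  trios <- pedigree_trios(ped)
  f <- tr$gm$calls[, trios$father[1]]; m <- tr$gm$calls[, trios$mother[1]]
  c_ <- tr$gm$calls[, trios$child[1]]
  both0 <- f == 0L & m == 0L
  expect_true(all(c_[both0] == 0L))
  # 100 meioses on a 100 cM chromosome: mean crossovers within 3 SE of 1.0
  k <- tr$crossovers$n_crossovers
  expect_equal(length(k), 100)
  expect_lt(abs(mean(k) - 1), 3 * sqrt(1 / 100))
  # zero-length map: each child haplotype equals one parental haplotype
  map0 <- genetic_map(data.frame(chrom = "chr1", pos = c(1, 1e8), cM = c(0, 0)),
                      fallback_rate = 1e-9)
  tr0 <- transmit_pedigree(fo, ped, map0, cfg, seed = 99)
  expect_true(all(tr0$crossovers$n_crossovers == 0))
  ch <- trios$child[1]
  h <- tr0$haplotypes$H1[, ch]
  fa <- trios$father[1]
  expect_true(identical(h, tr0$haplotypes$H1[, fa]) ||
              identical(h, tr0$haplotypes$H2[, fa]))
})

test_that("error injection hits the configured rate and is reproducible", {
  # 100 Mb all-homozygous genome at 4.5 flips/Mb: Poisson(450) within 3 SE
  sites <- data.frame(chrom = "chr1", pos = seq_len(20000) * 5000,
                      ref = "A", alt = "G", alt_af = 0.5)
  gm <- genotype_matrix(sites, matrix(0L, 20000, 1), "S1")
  cfg <- sim_config(seed = 6, chrom_lengths = c(chr1 = 1e8), het_error_rate = 4.5)
  err <- inject_errors(gm, cfg)
  n_flips <- sum(err$gm$calls == 1L)
  expect_lt(abs(n_flips - 450), 3 * sqrt(450))
  expect_equal(nrow(err$flips), n_flips)
  # identity at zero rates
  cfg0 <- sim_config(seed = 6, chrom_lengths = c(chr1 = 1e8), het_error_rate = 0)
  expect_identical(inject_errors(gm, cfg0)$gm$calls, gm$calls)
  # determinism: same seed -> identical output; flips recorded exactly
  err2 <- inject_errors(gm, cfg)
  expect_identical(err$gm$calls, err2$gm$calls)
  expect_identical(err$flips, err2$flips)
})

test_that("bad sites flip symmetrically and are recorded", {
  sites <- data.frame(chrom = "chr1", pos = seq_len(1000) * 1000,
                      ref = "A", alt = "G", alt_af = 0.5)
  calls <- matrix(rep(c(0L, 1L, 2L), length.out = 4000), 1000, 4)
  gm <- genotype_matrix(sites, calls, paste0("S", 1:4))
  cfg <- sim_config(seed = 7, chrom_lengths = c(chr1 = 1e6), het_error_rate = 0,
                    bad_site_fraction = 0.1, bad_site_error_prob = 0.5)
  err <- inject_errors(gm, cfg)
  expect_equal(nrow(err$bad_sites), 100)
  fl <- err$flips
  expect_true(all(fl$channel == "bad_site"))
  expect_true(all((fl$from %in% c(0L, 2L) & fl$to == 1L) |
                  (fl$from == 1L & fl$to %in% c(0L, 2L))))
})

test_that("array mask uses the floor rule and is seed-deterministic", {
  sites <- data.frame(chrom = "chr1", pos = seq_len(1000) * 1000)
  cfg <- sim_config(seed = 8, chrom_lengths = c(chr1 = 1e6), array_mask_fraction = 0.1)
  m1 <- make_array_mask(sites, cfg)
  expect_equal(nrow(m1), 100)
  expect_true(all(diff(m1$pos) > 0))
  m2 <- make_array_mask(sites, cfg)
  expect_identical(m1, m2)
  m3 <- make_array_mask(sites, cfg, seed = 1234)
  expect_false(identical(m1, m3))
  cfg1 <- sim_config(seed = 8, chrom_lengths = c(chr1 = 1e6), array_mask_fraction = 1)
  expect_equal(make_array_mask(sites, cfg1)$pos, sites$pos)
})

test_that("full cohort simulation is bit-reproducible and writable", {
  cfg <- sim_config(seed = 9, n_founders = 4, chrom_lengths = c(chr1 = 5e6),
                    site_density = 60, n_segments_short = 2, n_segments_long = 0,
                    het_error_rate = 2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gm$calls, b$gm$calls)
  expect_identical(a$truth, b$truth)
  expect_identical(a$mask, b$mask)
  dir <- withr::local_tempdir()
  paths <- write_cohort(a, dir)
  expect_true(all(file.exists(paths)))
  back <- read_vcf(paths["vcf"])
  expect_identical(back$calls, a$gm$calls)
})
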