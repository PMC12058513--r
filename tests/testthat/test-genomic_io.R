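test_that("VCF codes are mapped correctly and alt_af recomputed from calls", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
           "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t1/1",
           "chr1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/0\t0/0\t0/0")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f)
  # multiallelic record skipped by default
  expect_equal(nrow(gm$sites), 2)
  expect_equal(unname(gm$calls[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(gm$calls[2, ]), c(-1L, 1L, 2L))
  # AF from non-missing calls: 3 alt / 6 alleles; missing excluded
  expect_equal(gm$sites$alt_af, c(0.5, 0.75))
  expect_error(read_vcf(f, multiallelic = "error"), "multiallelic")
})

test_that("VCF round-trip preserves sites, sample order and codes exactly", {
  set.seed(42)
  calls <- matrix(sample(c(-1L, 0L, 1L, 2L), 60, replace = TRUE), 20, 3)
  gm <- make_gm(calls, pos = sort(sample.int(1e6, 20)))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  back <- read_vcf(f)
  expect_identical(back$calls, gm$calls)
  expect_identical(back$samples, gm$samples)
  expect_identical(back$sites[c("chrom", "pos", "ref", "alt")],
                   gm$sites[c("chrom", "pos", "ref", "alt")])
  expect_equal(back$sites$alt_af, gm$sites$alt_af, tolerance = 1e-5)
})

test_that("written VCF is read identically by an independent parser", {
  set.seed(7)
  calls <- matrix(sample(c(-1L, 0L, 1L, 2L), 30, replace = TRUE), 10, 3)
  gm <- make_gm(calls, pos = sort(sample.int(1e5, 10)))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  v <- VariantAnnotation::readVcf(f)
  gt <- VariantAnnotation::geno(v)$GT
  map <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L, "./." = -1L, "." = -1L)
  oracle <- matrix(map[gt], nrow(gt), ncol(gt))
  expect_equal(unname(oracle), unname(gm$calls))
})

test_that("genetic-map interpolation follows the anchor/extrapolation rules", {
  map <- genetic_map(data.frame(chrom = "chr1", pos = c(1, 1000001), cM = c(0, 1)),
                     fallback_rate = 1)
  expect_equal(interpolate_cM(map, "chr1", 500001), 0.5)
  expect_equal(interpolate_cM(map, "chr1", 1000001), 1)      # exact anchor
  expect_equal(interpolate_cM(map, "chr1", 1), 0)
  # before first anchor: first anchor's cM; beyond last: fallback 1 cM/Mb
  map2 <- genetic_map(data.frame(chrom = "chr1", pos = c(100, 1000001), cM = c(0.2, 1)))
  expect_equal(interpolate_cM(map2, "chr1", 50), 0.2)
  expect_equal(interpolate_cM(map, "chr1", 2000001), 2.0)
  expect_error(interpolate_cM(map, "chr9", 10), "not covered")
})

test_that("interpolate_cM is non-decreasing in position", {
  set.seed(1)
  anchors <- data.frame(chrom = "chr1", pos = sort(sample.int(1e7, 20)),
                        cM = cumsum(runif(20, 0, 2)))
  map <- genetic_map(anchors)
  q <- sort(sample.int(1.2e7, 500))
  cm <- interpolate_cM(map, "chr1", q)
  expect_true(all(diff(cm) >= -1e-12))
})

test_that("genetic map TSV round-trips with and without header", {
  map <- uniform_genetic_map(c(chr1 = 1e7, chr2 = 5e6), rate = 1.3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genetic_map(map, f)
  back <- read_genetic_map(f, fallback_rate = 1.3)
  expect_equal(back$chrom, map$chrom, tolerance = 1e-9)
  # headerless dialect
  writeLines(c("chr1\t1\t0", "chr1\t1000001\t1.5"), f)
  m2 <- read_genetic_map(f)
  expect_equal(interpolate_cM(m2, "chr1", 1000001), 1.5)
})

test_that("BED and GFF3 intervals unify to 1-based inclusive coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200", bed)
  iv <- read_intervals(bed)
  expect_equal(iv$start, 100)
  expect_equal(iv$end, 200)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1;Name=GENE1",
               "chr1\tsrc\texon\t100\t150\t.\t+\t.\tID=e1;Parent=g1"), gff)
  gv <- read_intervals(gff)
  expect_equal(nrow(gv), 1)  # only gene records
  expect_equal(gv$start, 100)
  expect_equal(gv$end, 200)
  expect_equal(gv$name, "GENE1")
  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_intervals(empty)), 0)
})

test_that("FAM round-trip and pedigree validation", {
  ped <- make_pedigree(trios = 1, septets = 1)
  expect_equal(nrow(ped), 10)
  f <- withr::local_tempfile(fileext = ".fam")
  write_fam(ped, f)
  back <- read_fam(f)
  expect_setequal(back$iid, ped$iid)
  expect_equal(nrow(pedigree_trios(back)), 4)  # 1 + 3
  # parents must precede children topologically
  idx <- match(back$iid, back$iid)
  for (i in seq_len(nrow(back))) {
    if (back$father[i] != "0")
      expect_lt(match(back$father[i], back$iid), i)
  }
  expect_error(pedigree(data.frame(fid = "F", iid = "A", father = "B", mother = "0")),
               "not present")
})
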