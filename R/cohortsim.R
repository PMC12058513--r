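#' Simulation configuration
#'
#' Describes a synthetic cohort: site spectrum, pedigree structure, planted
#' autozygosity in two length regimes, and the genotype-error model.
#'
#' @param seed master RNG seed.
#' @param n_founders unrelated founders to simulate when no pedigree is
#'   given (ignored when `pedigree_spec` is set).
#' @param pedigree_spec optional named list `list(trios=, septets=, octets=)`
#'   of three-generation family templates (a septet is 4 grandparents, 2
#'   parents, 1 child; an octet adds a second child).
#' @param chrom_lengths named numeric vector, chromosome -> bp.
#' @param site_density variant sites per Mb (default 100; site counts are
#'   fixed at `round(length * density)` with uniformly scattered positions).
#' @param af_shape Beta shape parameters for the alternate-allele frequency
#'   (default `c(2, 2)`: a mid-frequency common-variant spectrum, matching a
#'   cohort already AF-filtered to [0.05, 0.95]).
#' @param n_segments_short,n_segments_long planted autozygous segments per
#'   founder in the short (100 Kb - 1.5 Mb, uniform lengths) and long
#'   (1.5 Mb + Exp(`long_mean_excess_bp`)) regimes; defaults 10 and 3.
#' @param short_range_bp length range of the short regime
#'   (default `c(1e5, 1.5e6)`).
#' @param long_mean_excess_bp mean exponential excess above 1.5 Mb for long
#'   segments (default 2 Mb).
#' @param het_error_rate expected spurious heterozygote calls per Mb per
#'   sample (default 4.5, the rate reported for Japanese high-coverage WGS).
#' @param bad_site_fraction fraction of sites designated systematic-error
#'   sites (default 0).
#' @param bad_site_error_prob per-genotype flip probability at bad sites
#'   (default 0).
#' @param array_mask_fraction fraction of sites retained in the array mask
#'   (default 0.25, ~700K array sites vs a multi-million-site WGS panel
#'   scaled to desk size).
#' @param rec_rate_cM_per_Mb recombination rate of the simulated uniform
#'   genetic map (default 1).
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_founders = 50L, pedigree_spec = NULL,
                       chrom_lengths = c(chr1 = 5e7), site_density = 100,
                       af_shape = c(2, 2),
                       n_segments_short = 10L, n_segments_long = 3L,
                       short_range_bp = c(1e5, 1.5e6), long_mean_excess_bp = 2e6,
                       het_error_rate = 4.5, bad_site_fraction = 0,
                       bad_site_error_prob = 0, array_mask_fraction = 0.25,
                       rec_rate_cM_per_Mb = 1) {
  stopifnot(site_density > 0, all(chrom_lengths > 0), length(chrom_lengths) >= 1,
            all(af_shape > 0), het_error_rate >= 0,
            bad_site_fraction >= 0, bad_site_fraction <= 1,
            bad_site_error_prob >= 0, bad_site_error_prob <= 1,
            array_mask_fraction > 0, array_mask_fraction <= 1,
            short_range_bp[1] > 0, short_range_bp[2] >= short_range_bp[1])
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  if (!is.null(pedigree_spec)) {
    sizes <- c(trios = 3L, septets = 7L, octets = 8L)
    if (!all(names(pedigree_spec) %in% names(sizes)))
      stop("pedigree_spec entries must be trios/septets/octets")
  }
  structure(list(seed = as.integer(seed), n_founders = as.integer(n_founders),
                 pedigree_spec = pedigree_spec, chrom_lengths = chrom_lengths,
                 site_density = site_density, af_shape = af_shape,
                 n_segments_short = as.integer(n_segments_short),
                 n_segments_long = as.integer(n_segments_long),
                 short_range_bp = short_range_bp,
                 long_mean_excess_bp = long_mean_excess_bp,
                 het_error_rate = het_error_rate,
                 bad_site_fraction = bad_site_fraction,
                 bad_site_error_prob = bad_site_error_prob,
                 array_mask_fraction = array_mask_fraction,
                 rec_rate_cM_per_Mb = rec_rate_cM_per_Mb),
            class = "SimConfig")
}

#' Simulate variant sites
#'
#' Fixed per-chromosome counts `round(length_bp * density / 1e6)`, positions
#' drawn uniformly without replacement (strictly increasing), alternate-allele
#' frequencies from the configured Beta law, clipped inside (0, 1).
#'
#' @param config a [sim_config()].
#' @return data.frame: `chrom`, `pos`, `ref`, `alt`, `alt_af`.
#' @export
simulate_sites <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  out <- lapply(names(config$chrom_lengths), function(ch) {
    L <- config$chrom_lengths[[ch]]
    n <- round(L * config$site_density / 1e6)
    if (n < 1) stop("chromosome ", ch, " too short for the configured site density")
    pos <- sort(sample.int(L, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    af <- stats::rbeta(n, config$af_shape[1], config$af_shape[2])
    af <- pmin(pmax(af, 1e-6), 1 - 1e-6)
    data.frame(chrom = ch, pos = pos, ref = ref, alt = alt, alt_af = af,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

## draw non-overlapping planted intervals on one chromosome; simple rejection
plant_intervals <- function(L, lengths, max_tries = 1000) {
  placed <- data.frame(start = numeric(0), end = numeric(0))
  for (len in lengths) {
    if (len > L) stop("planted segment longer than its chromosome")
    for (t in seq_len(max_tries)) {
      s <- sample.int(L - len + 1, 1)
      e <- s + len - 1
      if (!any(s <= placed$end & e >= placed$start)) {
        placed <- rbind(placed, data.frame(start = s, end = e))
        break
      }
      if (t == max_tries) stop("could not place planted segments without overlap")
    }
  }
  placed  # in input (lengths) order; caller sorts
}

#' Simulate founder genotypes with planted autozygosity
#'
#' Founders draw two haplotypes per site from Bernoulli(alt_af)
#' (Hardy-Weinberg). Within each planted interval one haplotype is copied
#' over the other, so every genotype inside is homozygous by construction and
#' the truth set records the interval exactly.
#'
#' @param sites output of [simulate_sites()] (must be sorted).
#' @param config a [sim_config()]; the RNG state is seeded from
#'   `config$seed + 1`.
#' @param founder_ids optional founder identifiers (default
#'   `S001..S<n_founders>`).
#' @return List: `gm` (founder `GenotypeMatrix`), `haplotypes` (list of two
#'   0/1 matrices), `truth` (data.frame `sample`, `chrom`, `start`, `end`,
#'   `regime`).
#' @export
simulate_founders <- function(sites, config, founder_ids = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(founder_ids))
    founder_ids <- sprintf("S%03d", seq_len(config$n_founders))
  set.seed(config$seed + 1L)
  n <- nrow(sites); m <- length(founder_ids)
  H1 <- matrix(stats::rbinom(n * m, 1, sites$alt_af), n, m)
  H2 <- matrix(stats::rbinom(n * m, 1, sites$alt_af), n, m)
  truth <- list()
  for (j in seq_len(m)) {
    for (ch in names(config$chrom_lengths)) {
      L <- config$chrom_lengths[[ch]]
      lens <- c(
        if (config$n_segments_short > 0)
          round(stats::runif(config$n_segments_short,
                             config$short_range_bp[1], config$short_range_bp[2])),
        if (config$n_segments_long > 0)
          round(1.5e6 + stats::rexp(config$n_segments_long,
                                    1 / config$long_mean_excess_bp)))
      if (!length(lens)) next
      regime <- c(rep("short", config$n_segments_short),
                  rep("long", config$n_segments_long))
      ord <- order(lens, decreasing = TRUE)   # place large segments first
      iv <- plant_intervals(L, lens[ord])
      iv$regime <- regime[ord]
      iv <- iv[order(iv$start), , drop = FALSE]
      on_ch <- sites$chrom == ch
      for (k in seq_len(nrow(iv))) {
        inside <- on_ch & sites$pos >= iv$start[k] & sites$pos <= iv$end[k]
        H2[inside, j] <- H1[inside, j]
      }
      truth[[length(truth) + 1]] <- data.frame(
        sample = founder_ids[j], chrom = ch, start = iv$start, end = iv$end,
        regime = iv$regime, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), regime = character(0))
  rownames(truth) <- NULL
  gm <- genotype_matrix(sites, H1 + H2, founder_ids)
  list(gm = gm, haplotypes = list(H1 = H1, H2 = H2), truth = truth)
}

## one gamete: recombinant mosaic of h1/h2 (vectors over sites of one chrom)
## under the Haldane model. Returns list(haplotype, n_crossovers).
make_gamete <- function(h1, h2, pos, map, chrom, chrom_len) {
  cm_total <- map_cM_length(map, chrom, chrom_len)
  k <- stats::rpois(1, cm_total / 100)
  cur <- sample.int(2, 1)
  if (k == 0) {
    hap <- if (cur == 1) h1 else h2
    return(list(haplotype = hap, n_crossovers = 0L))
  }
  cm0 <- interpolate_cM(map, chrom, 1)
  xo_cm <- sort(stats::runif(k, 0, cm_total)) + cm0
  xo_bp <- map_cM_to_bp(map, chrom, xo_cm)
  ## segment index at each site = number of crossovers at or before the site;
  ## haplotype alternates from the starting choice at every crossover
  seg <- findInterval(pos, xo_bp)
  hap <- ifelse((seg %% 2 == 0) == (cur == 1), h1, h2)
  list(haplotype = hap, n_crossovers = as.integer(k))
}

#' Transmit founder haplotypes through a pedigree
#'
#' Each offspring haplotype is a recombinant mosaic of one parent's two
#' haplotypes; crossover counts are Poisson in map length (Haldane, no
#' interference) with positions uniform on the cM scale. Before error
#' injection, every trio is Mendelian-consistent at every site by
#' construction.
#'
#' @param founders output of [simulate_founders()] whose `gm$samples` cover
#'   the pedigree founders.
#' @param ped a `Pedigree`; founders must be genotyped, every non-founder
#'   must have both parents in the pedigree.
#' @param map a `GeneticMap` covering all chromosomes.
#' @param config the [sim_config()] (for chromosome lengths).
#' @param seed RNG seed (default `config$seed + 2`).
#' @return List: `gm` (all pedigree members), `haplotypes`, and
#'   `crossovers` (data.frame `child`, `chrom`, `parent`, `n_crossovers`).
#' @export
transmit_pedigree <- function(founders, ped, map, config, seed = NULL) {
  stopifnot(inherits(ped, "Pedigree"), inherits(map, "GeneticMap"))
  if (is.null(seed)) seed <- config$seed + 2L
  set.seed(seed)
  sites <- founders$gm$sites
  fnd <- pedigree_founders(ped)
  if (!all(fnd %in% founders$gm$samples))
    stop("pedigree founder missing from simulated founders")
  non_fnd <- setdiff(ped$iid, fnd)
  if (any(ped$father[match(non_fnd, ped$iid)] == "0" |
          ped$mother[match(non_fnd, ped$iid)] == "0"))
    stop("every non-founder must have both parents present")
  n <- nrow(sites)
  ids <- ped$iid
  H1 <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  H2 <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  fidx <- match(fnd, founders$gm$samples)
  H1[, fnd] <- founders$haplotypes$H1[, fidx]
  H2[, fnd] <- founders$haplotypes$H2[, fidx]
  xo <- list()
  for (id in ids) {                      # pedigree rows are topologically sorted
    r <- ped[ped$iid == id, ]
    if (r$father == "0") next
    for (ch in names(config$chrom_lengths)) {
      on_ch <- which(sites$chrom == ch)
      pos <- sites$pos[on_ch]
      gp <- make_gamete(H1[on_ch, r$father], H2[on_ch, r$father], pos, map, ch,
                        config$chrom_lengths[[ch]])
      gmat <- make_gamete(H1[on_ch, r$mother], H2[on_ch, r$mother], pos, map, ch,
                          config$chrom_lengths[[ch]])
      H1[on_ch, id] <- gp$haplotype
      H2[on_ch, id] <- gmat$haplotype
      xo[[length(xo) + 1]] <- data.frame(
        child = id, chrom = ch, parent = c("father", "mother"),
        n_crossovers = c(gp$n_crossovers, gmat$n_crossovers),
        stringsAsFactors = FALSE)
    }
  }
  gm <- genotype_matrix(sites, H1 + H2, ids)
  list(gm = gm, haplotypes = list(H1 = H1, H2 = H2),
       crossovers = if (length(xo)) do.call(rbind, xo) else NULL)
}

#' Inject genotyping errors
#'
#' Two error channels: (1) spurious heterozygotes — per sample,
#' `Poisson(het_error_rate * genome_Mb)` homozygous calls drawn uniformly
#' over that sample's homozygous sites are flipped to heterozygous;
#' (2) systematic bad sites — a fixed fraction of sites at which every
#' sample's genotype flips independently with `bad_site_error_prob`
#' (hom -> het, het -> a random homozygote), producing recurrent Mendelian
#' inconsistencies. All flips are recorded.
#'
#' @param gm a `GenotypeMatrix`.
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed + 3`).
#' @return List: `gm` (with errors), `flips` (data.frame `sample`, `chrom`,
#'   `pos`, `from`, `to`, `channel`), `bad_sites` (data.frame `chrom`,
#'   `pos`).
#' @export
inject_errors <- function(gm, config, seed = NULL) {
  stopifnot(inherits(gm, "GenotypeMatrix"), inherits(config, "SimConfig"))
  if (is.null(seed)) seed <- config$seed + 3L
  set.seed(seed)
  calls <- gm$calls
  genome_mb <- sum(config$chrom_lengths) / 1e6
  flips <- list()
  if (config$het_error_rate > 0) {
    for (j in seq_along(gm$samples)) {
      hom <- which(calls[, j] == 0L | calls[, j] == 2L)
      if (!length(hom)) next
      k <- min(stats::rpois(1, config$het_error_rate * genome_mb), length(hom))
      if (k == 0) next
      at <- sample(hom, k)
      flips[[length(flips) + 1]] <- data.frame(
        sample = gm$samples[j], chrom = gm$sites$chrom[at], pos = gm$sites$pos[at],
        from = calls[at, j], to = 1L, channel = "het_error", stringsAsFactors = FALSE)
      calls[at, j] <- 1L
    }
  }
  bad_sites <- data.frame(chrom = character(0), pos = integer(0))
  if (config$bad_site_fraction > 0 && config$bad_site_error_prob > 0) {
    nb <- floor(config$bad_site_fraction * nrow(gm$sites))
    bad_idx <- sort(sample.int(nrow(gm$sites), nb))
    bad_sites <- gm$sites[bad_idx, c("chrom", "pos")]
    for (j in seq_along(gm$samples)) {
      hit <- bad_idx[stats::runif(length(bad_idx)) < config$bad_site_error_prob]
      hit <- hit[calls[hit, j] >= 0L]
      if (!length(hit)) next
      from <- calls[hit, j]
      to <- ifelse(from == 1L, sample(c(0L, 2L), length(hit), replace = TRUE), 1L)
      flips[[length(flips) + 1]] <- data.frame(
        sample = gm$samples[j], chrom = gm$sites$chrom[hit], pos = gm$sites$pos[hit],
        from = from, to = as.integer(to), channel = "bad_site", stringsAsFactors = FALSE)
      calls[hit, j] <- as.integer(to)
    }
  }
  flips <- if (length(flips)) do.call(rbind, flips) else
    data.frame(sample = character(0), chrom = character(0), pos = integer(0),
               from = integer(0), to = integer(0), channel = character(0))
  rownames(flips) <- NULL; rownames(bad_sites) <- NULL
  out <- gm; out$calls <- calls
  list(gm = out, flips = flips, bad_sites = bad_sites)
}

#' Draw an array-site mask
#'
#' Uniform subsample of `floor(fraction * n_sites)` sites without
#' replacement, sorted — a stand-in for a SNP-array manifest.
#'
#' @param sites site table (`chrom`, `pos`).
#' @param config a [sim_config()] (uses `array_mask_fraction`).
#' @param seed RNG seed (default `config$seed + 4`).
#' @return data.frame: `chrom`, `pos`.
#' @export
make_array_mask <- function(sites, config, seed = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$array_mask_fraction <= 0) stop("array_mask_fraction must be positive")
  if (is.null(seed)) seed <- config$seed + 4L
  set.seed(seed)
  k <- floor(config$array_mask_fraction * nrow(sites))
  idx <- sort(sample.int(nrow(sites), k))
  out <- sites[idx, c("chrom", "pos")]
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort
#'
#' Runs the whole generator: sites, founders with planted autozygosity,
#' optional pedigree transmission, error injection, array mask and a uniform
#' genetic map. The pre-error matrix is kept alongside the errorful one so
#' recovery and error-effect analyses share a single ground truth.
#'
#' @param config a [sim_config()].
#' @return List: `gm` (post-error), `gm_clean` (pre-error), `truth`,
#'   `flips`, `bad_sites`, `pedigree` (NULL without `pedigree_spec`), `map`,
#'   `mask`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  sites <- simulate_sites(config)
  map <- uniform_genetic_map(config$chrom_lengths, config$rec_rate_cM_per_Mb)
  ped <- NULL
  if (!is.null(config$pedigree_spec)) {
    ped <- do.call(make_pedigree, config$pedigree_spec)
    fnd <- pedigree_founders(ped)
    cfg <- config; cfg$n_founders <- length(fnd)
    founders <- simulate_founders(sites, cfg, founder_ids = fnd)
    tr <- transmit_pedigree(founders, ped, map, config)
    gm_clean <- tr$gm
    truth <- founders$truth
  } else {
    founders <- simulate_founders(sites, config)
    gm_clean <- founders$gm
    truth <- founders$truth
  }
  err <- inject_errors(gm_clean, config)
  mask <- make_array_mask(sites, config)
  list(gm = err$gm, gm_clean = gm_clean, truth = truth, flips = err$flips,
       bad_sites = err$bad_sites, pedigree = ped, map = map, mask = mask,
       config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits the standard formats: multi-sample VCF, FAM, genetic-map TSV, truth
#' and mask BED, and the configuration as JSON.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    map = file.path(dir, "genetic_map.tsv"),
    truth = file.path(dir, "truth_segments.bed"),
    mask = file.path(dir, "array_mask.bed"),
    config = file.path(dir, "config.json"))
  write_vcf(cohort$gm, paths["vcf"], contig_lengths = cohort$config$chrom_lengths)
  write_genetic_map(cohort$map, paths["map"])
  write_bed(data.frame(chrom = cohort$truth$chrom, start = cohort$truth$start,
                       end = cohort$truth$end, name = cohort$truth$sample),
            paths["truth"])
  write_bed(data.frame(chrom = cohort$mask$chrom, start = cohort$mask$pos,
                       end = cohort$mask$pos), paths["mask"])
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  if (!is.null(cohort$pedigree)) {
    paths <- c(paths, fam = file.path(dir, "cohort.fam"))
    write_fam(cohort$pedigree, paths["fam"])
  }
  invisible(paths)
}
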