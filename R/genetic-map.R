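#' Construct a genetic map
#'
#' A per-chromosome monotone lookup from physical position (bp) to cumulative
#' genetic distance (cM), used both to scale the HMM transition probabilities
#' and to place simulated crossovers.
#'
#' @param anchors data.frame with columns `chrom`, `pos` (bp) and `cM`
#'   (cumulative centimorgans); per chromosome, `pos` must be strictly
#'   increasing and `cM` non-decreasing.
#' @param fallback_rate cM/Mb rate used to extrapolate beyond the last anchor
#'   (default 1 cM/Mb, roughly the genome-wide human average).
#' @return An object of class `GeneticMap`.
#' @export
genetic_map <- function(anchors, fallback_rate = 1) {
  stopifnot(is.data.frame(anchors), all(c("chrom", "pos", "cM") %in% names(anchors)))
  anchors$chrom <- as.character(anchors$chrom)
  sp <- split(anchors[c("pos", "cM")], anchors$chrom)
  for (ch in names(sp)) {
    sp[[ch]] <- sp[[ch]][order(sp[[ch]]$pos), , drop = FALSE]
    rownames(sp[[ch]]) <- NULL
    if (anyDuplicated(sp[[ch]]$pos))
      stop("duplicate anchor positions on ", ch)
    if (is.unsorted(sp[[ch]]$cM))
      stop("cumulative cM must be non-decreasing on ", ch)
  }
  structure(list(chrom = sp, fallback_rate = fallback_rate), class = "GeneticMap")
}

#' Read a genetic map from a 3-column TSV
#'
#' Expects columns (chrom, pos, cM); a header line is auto-detected.
#'
#' @param path file path.
#' @param fallback_rate see [genetic_map()].
#' @return A `GeneticMap`.
#' @export
read_genetic_map <- function(path, fallback_rate = 1) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t|\\s+")[[1]][2])))
  dt <- data.table::fread(path, header = has_header)
  if (ncol(dt) < 3) stop("genetic map must have 3 columns: chrom, pos, cM")
  anchors <- data.frame(chrom = as.character(dt[[1]]), pos = as.numeric(dt[[2]]),
                        cM = as.numeric(dt[[3]]))
  genetic_map(anchors, fallback_rate)
}

#' Write a genetic map as 3-column TSV
#' @param map a `GeneticMap`.
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  df <- do.call(rbind, lapply(names(map$chrom), function(ch)
    data.frame(chrom = ch, pos = map$chrom[[ch]]$pos, cM = map$chrom[[ch]]$cM)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Uniform genetic map at a constant recombination rate
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param rate cM/Mb (default 1).
#' @param anchor_spacing_bp distance between anchors (default 5 Mb).
#' @return A `GeneticMap`.
#' @export
uniform_genetic_map <- function(chrom_lengths, rate = 1, anchor_spacing_bp = 5e6) {
  anchors <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    pos <- unique(c(seq(1, chrom_lengths[[ch]], by = anchor_spacing_bp), chrom_lengths[[ch]]))
    data.frame(chrom = ch, pos = pos, cM = (pos - 1) * rate / 1e6)
  }))
  genetic_map(anchors, fallback_rate = rate)
}

#' Interpolate genetic-map position
#'
#' Linear interpolation between flanking anchors. Positions before the first
#' anchor take the first anchor's cM (zero offset); positions beyond the last
#' anchor extrapolate at the map's fallback rate (cM/Mb).
#'
#' @param map a `GeneticMap`.
#' @param chrom chromosome name (scalar).
#' @param pos numeric vector of bp positions.
#' @return Numeric vector of cumulative cM, same length as `pos`.
#' @export
interpolate_cM <- function(map, chrom, pos) {
  stopifnot(inherits(map, "GeneticMap"))
  tab <- map$chrom[[as.character(chrom)]]
  if (is.null(tab))
    stop("chromosome ", chrom, " not covered by the genetic map")
  n <- nrow(tab)
  cm <- stats::approx(tab$pos, tab$cM, xout = pos, rule = 2, ties = "ordered")$y
  if (n == 1L) cm <- rep(tab$cM, length(pos))
  beyond <- pos > tab$pos[n]
  if (any(beyond))
    cm[beyond] <- tab$cM[n] + (pos[beyond] - tab$pos[n]) * map$fallback_rate / 1e6
  cm
}

## inverse lookup: cumulative cM -> bp on one chromosome (for crossover placement)
map_cM_to_bp <- function(map, chrom, cm) {
  tab <- map$chrom[[as.character(chrom)]]
  n <- nrow(tab)
  ## flat (0-rate) stretches are handled by approx ties; strictly increasing cM
  ## is the normal case for simulated maps
  if (n == 1L || tab$cM[n] == tab$cM[1])
    return(rep(tab$pos[1], length(cm)))
  bp <- stats::approx(tab$cM, tab$pos, xout = cm, rule = 2, ties = "ordered")$y
  beyond <- cm > tab$cM[n]
  if (any(beyond))
    bp[beyond] <- tab$pos[n] + (cm[beyond] - tab$cM[n]) * 1e6 / map$fallback_rate
  bp
}

## total cM length of a chromosome up to length_bp
map_cM_length <- function(map, chrom, length_bp) {
  interpolate_cM(map, chrom, length_bp) - interpolate_cM(map, chrom, 1)
}
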