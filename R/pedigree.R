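#' Construct a pedigree
#'
#' A founder/offspring graph in PLINK FAM layout: family id, individual id,
#' father, mother ("0" = missing), sex (1 male / 2 female / 0 unknown),
#' phenotype.
#'
#' @param df data.frame with columns `fid`, `iid`, `father`, `mother`, `sex`,
#'   `phenotype` (last two optional; default 0 / -9).
#' @return An object of class `Pedigree`: the validated data.frame, rows in a
#'   topological order (parents before children).
#' @export
pedigree <- function(df) {
  stopifnot(is.data.frame(df), all(c("fid", "iid", "father", "mother") %in% names(df)))
  df$fid <- as.character(df$fid); df$iid <- as.character(df$iid)
  df$father <- as.character(df$father); df$mother <- as.character(df$mother)
  if (is.null(df$sex)) df$sex <- 0L
  if (is.null(df$phenotype)) df$phenotype <- -9L
  if (anyDuplicated(df$iid)) stop("duplicate individual ids in pedigree")
  known <- c("0", df$iid)
  if (!all(df$father %in% known) || !all(df$mother %in% known))
    stop("pedigree references a parent that is not present (use \"0\" for missing)")
  ## topological sort; also detects cycles
  ord <- character(0)
  placed <- stats::setNames(rep(FALSE, nrow(df)), df$iid)
  remaining <- df$iid
  while (length(remaining)) {
    ready <- vapply(remaining, function(id) {
      r <- df[df$iid == id, ]
      (r$father == "0" || placed[[r$father]]) && (r$mother == "0" || placed[[r$mother]])
    }, logical(1))
    if (!any(ready)) stop("pedigree is cyclic or inconsistent")
    ord <- c(ord, remaining[ready])
    placed[remaining[ready]] <- TRUE
    remaining <- remaining[!ready]
  }
  df <- df[match(ord, df$iid), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("Pedigree", "data.frame"))
}

#' Read a PLINK 6-column FAM file
#' @param path file path.
#' @return A `Pedigree`.
#' @export
read_fam <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("fid", "iid", "father", "mother", "sex", "phenotype"))
  pedigree(as.data.frame(dt))
}

#' Write a pedigree as a PLINK FAM file
#' @param ped a `Pedigree`.
#' @param path output path.
#' @export
write_fam <- function(ped, path) {
  data.table::fwrite(as.data.frame(ped)[c("fid", "iid", "father", "mother", "sex", "phenotype")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Founders of a pedigree
#' @param ped a `Pedigree`.
#' @return Character vector of individual ids with both parents missing.
#' @export
pedigree_founders <- function(ped) ped$iid[ped$father == "0" & ped$mother == "0"]

#' Parent-parent-child trios of a pedigree
#'
#' Multi-generation families are decomposed into their constituent trios; an
#' individual with both parents present contributes one trio.
#'
#' @param ped a `Pedigree`.
#' @return data.frame with columns `father`, `mother`, `child`, `fid`.
#' @export
pedigree_trios <- function(ped) {
  keep <- ped$father != "0" & ped$mother != "0"
  data.frame(father = ped$father[keep], mother = ped$mother[keep],
             child = ped$iid[keep], fid = ped$fid[keep], stringsAsFactors = FALSE)
}

#' Build a pedigree from family templates
#'
#' Templates mirror a three-generation cohort design: `trio` = two founders
#' and a child (3 members, 1 trio); `septet` = four grandparents, two parents,
#' one grandchild (7 members, 3 trios); `octet` = a septet with a second
#' grandchild (8 members, 4 trios).
#'
#' @param trios,septets,octets number of families of each template.
#' @return A `Pedigree` covering all families, ids `F<k>_I<j>`.
#' @export
make_pedigree <- function(trios = 0, septets = 0, octets = 0) {
  rows <- list(); k <- 0
  add_fam <- function(members) {
    k <<- k + 1
    fid <- sprintf("F%03d", k)
    members$iid <- sprintf("%s_%s", fid, members$iid)
    nz <- members$father != "0"
    members$father[nz] <- sprintf("%s_%s", fid, members$father[nz])
    nz <- members$mother != "0"
    members$mother[nz] <- sprintf("%s_%s", fid, members$mother[nz])
    members$fid <- fid
    rows[[length(rows) + 1]] <<- members
  }
  trio_tpl <- data.frame(iid = c("P1", "P2", "C1"),
                         father = c("0", "0", "P1"), mother = c("0", "0", "P2"),
                         sex = c(1L, 2L, 0L), stringsAsFactors = FALSE)
  septet_tpl <- data.frame(
    iid = c("GP1", "GP2", "GP3", "GP4", "P1", "P2", "C1"),
    father = c("0", "0", "0", "0", "GP1", "GP3", "P1"),
    mother = c("0", "0", "0", "0", "GP2", "GP4", "P2"),
    sex = c(1L, 2L, 1L, 2L, 1L, 2L, 0L), stringsAsFactors = FALSE)
  octet_tpl <- rbind(septet_tpl,
                     data.frame(iid = "C2", father = "P1", mother = "P2", sex = 0L))
  for (i in seq_len(trios)) add_fam(trio_tpl)
  for (i in seq_len(septets)) add_fam(septet_tpl)
  for (i in seq_len(octets)) add_fam(octet_tpl)
  if (!length(rows)) stop("at least one family is required")
  df <- do.call(rbind, rows)
  df$phenotype <- -9L
  pedigree(df)
}
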