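#' Density-matched pruning with iteration averaging
#'
#' Emulates comparing cohorts of unequal marker density: each iteration
#' samples `target_site_count` sites uniformly without replacement (site
#' order preserved), reruns the caller, and NROH is averaged first within
#' iteration across individuals, then across iterations. Iteration seeds are
#' derived as `seed + iteration` so single iterations reproduce in isolation.
#'
#' @param gm a filtered `GenotypeMatrix`.
#' @param target_site_count sites to retain per iteration
#'   (<= `nrow(gm$sites)`).
#' @param n_iterations number of iterations (default 10).
#' @param seed master seed.
#' @param caller `"hmm"` (default) or `"window"`.
#' @param map optional `GeneticMap` (HMM caller).
#' @param params caller parameters ([hmm_params()] or [window_params()]).
#' @param classes minimal-length thresholds in bp (default 100 Kb and
#'   1.5 Mb).
#' @return List: `mean_nroh` (named by class), `per_iteration` (data.frame
#'   `iteration`, `class_bp`, `mean_nroh`).
#' @export
density_prune_run <- function(gm, target_site_count, n_iterations = 10, seed = 1L,
                              caller = c("hmm", "window"), map = NULL, params = NULL,
                              classes = c(1e5, 1.5e6)) {
  caller <- match.arg(caller)
  n <- nrow(gm$sites)
  if (target_site_count > n) stop("target_site_count exceeds available sites")
  if (is.null(params)) params <- if (caller == "hmm") hmm_params() else window_params()
  rows <- list()
  for (it in seq_len(n_iterations)) {
    set.seed(seed + it)
    idx <- sort(sample.int(n, target_site_count))
    sub <- subset_sites(gm, idx)
    calls <- if (caller == "hmm") call_roh_hmm(sub, map, params) else
      call_roh_window(sub, params)
    for (cl in classes) {
      ns <- nroh_sroh(calls, cl, samples = gm$samples)
      rows[[length(rows) + 1]] <- data.frame(iteration = it, class_bp = cl,
                                             mean_nroh = mean(ns$nroh),
                                             mean_sroh = mean(ns$sroh))
    }
  }
  per_it <- do.call(rbind, rows)
  mean_nroh <- vapply(classes, function(cl)
    mean(per_it$mean_nroh[per_it$class_bp == cl]), numeric(1))
  names(mean_nroh) <- format(classes, scientific = FALSE, trim = TRUE)
  list(mean_nroh = mean_nroh, per_iteration = per_it)
}

#' Experiment plan
#'
#' @param callers subset of `c("hmm", "window")`.
#' @param region_sets subset of `c("all_sites", "array_mask")`.
#' @param window_het_values heterozygote allowances for the window caller
#'   (default 1).
#' @param classes minimal-length thresholds in bp.
#' @param prune_target optional site count for density pruning.
#' @param n_iterations pruning iterations (default 10).
#' @param mendel_filter apply Mendelian site removal before calling
#'   (requires a pedigree in the cohort).
#' @param seed master seed.
#' @return An `ExperimentPlan` list.
#' @export
experiment_plan <- function(callers = c("hmm", "window"),
                            region_sets = c("all_sites", "array_mask"),
                            window_het_values = 1L, classes = c(1e5, 1.5e6),
                            prune_target = NULL, n_iterations = 10,
                            mendel_filter = FALSE, seed = 1L) {
  stopifnot(all(callers %in% c("hmm", "window")),
            all(region_sets %in% c("all_sites", "array_mask")), n_iterations >= 1)
  structure(list(callers = callers, region_sets = region_sets,
                 window_het_values = window_het_values, classes = classes,
                 prune_target = prune_target, n_iterations = n_iterations,
                 mendel_filter = mendel_filter, seed = as.integer(seed)),
            class = "ExperimentPlan")
}

#' Cohort-summary comparison report
#'
#' One row per (caller, region set, het option, minimal-length class) with
#' the cohort mean NROH and SROH — the layout of a tool-by-region summary
#' table. A JSON-able run manifest records seeds and parameters.
#'
#' @param plan an [experiment_plan()].
#' @param cohort a [simulate_cohort()] result (or a list with `gm`, `mask`,
#'   `map`, optionally `pedigree`).
#' @param hmm_par,win_par caller parameter objects.
#' @return List: `table` (the summary data.frame), `manifest`.
#' @export
comparison_report <- function(plan, cohort, hmm_par = hmm_params(),
                              win_par = window_params()) {
  stopifnot(inherits(plan, "ExperimentPlan"))
  gm0 <- cohort$gm
  if (isTRUE(plan$mendel_filter)) {
    if (is.null(cohort$pedigree)) stop("mendel_filter requires a pedigree")
    rep <- site_error_scan(gm0, cohort$pedigree)
    gm0 <- remove_flagged_sites(gm0, rep)
  }
  filtered <- filter_sites(gm0)$gm
  rows <- list()
  for (region in plan$region_sets) {
    gm <- if (region == "array_mask") trim_to_mask(filtered, cohort$mask) else filtered
    for (caller in plan$callers) {
      hets <- if (caller == "window") plan$window_het_values else NA
      for (H in hets) {
        calls <- if (caller == "hmm") {
          call_roh_hmm(gm, cohort$map, hmm_par)
        } else {
          p <- win_par; p$window_het <- as.integer(H)
          call_roh_window(gm, p)
        }
        for (cl in plan$classes) {
          ns <- nroh_sroh(calls, cl, samples = gm$samples)
          rows[[length(rows) + 1]] <- data.frame(
            caller = caller, region_set = region, window_het = H, class_bp = cl,
            mean_nroh = mean(ns$nroh), mean_sroh = mean(ns$sroh),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  manifest <- list(seed = plan$seed, plan = unclass(plan),
                   hmm_params = unclass(hmm_par), window_params = unclass(win_par),
                   n_samples = length(cohort$gm$samples),
                   n_sites_input = nrow(cohort$gm$sites),
                   n_sites_filtered = nrow(filtered$sites),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  list(table = table, manifest = manifest)
}
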