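#' Run a reproducible multi-stage analysis
#'
#' Executes the requested stages in dependency order and writes every
#' stage's outputs plus full provenance (the config itself, the global
#' seed, per-stage seeds and package version) into an output directory, so
#' a run directory always contains enough metadata to reproduce itself.
#' The global seed is expanded into deterministic per-stage seeds (see
#' `derive_seed`), so stages can be re-run in isolation.
#'
#' Supported stages:
#' \describe{
#'   \item{`spatial`}{simulate tissue (or read `cell_table` CSV), build
#'     density maps for `TF_A`/`TF_B`, derive hotspots, measure immune-cell
#'     distances to both hotspot classes.}
#'   \item{`cohort`}{simulate an expression cohort (or read `expression` /
#'     `survival` inputs plus a `signature` GMT), score it, stratify into
#'     quartiles and fit the upper-vs-lower Cox hazard ratio.}
#'   \item{`microdissect`}{simulate dual-species reads (or read a `pairs`
#'     TSV), assign species and write compartment counts.}
#' }
#'
#' @param config Named list (or path to a JSON file): `stages` (character
#'   vector), `seed`, `out_dir`, optional stage parameter sublists
#'   `spatial`, `cohort`, `microdissect` and input paths. Unknown top-level
#'   keys are rejected.
#' @return The output directory path, invisibly; per-stage results as the
#'   `results` attribute.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("stages", "seed", "out_dir", "spatial", "cohort", "microdissect",
             "inputs")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    stop_spatsig("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("stages", "seed", "out_dir")) {
    if (is.null(config[[key]])) stop_spatsig("config is missing '", key, "'")
  }
  stages <- config$stages
  bad <- setdiff(stages, c("spatial", "cohort", "microdissect"))
  if (length(bad) > 0L) stop_spatsig("unknown stage(s): ", paste(bad, collapse = ", "))
  inputs <- config$inputs
  # fail before any stage runs if a named input path is absent
  for (p in unlist(inputs)) {
    if (!file.exists(p)) stop_spatsig("input path does not exist: ", p)
  }

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stage_seeds <- stats::setNames(
    vapply(seq_along(stages), function(i) derive_seed(config$seed, i), integer(1L)),
    stages
  )

  for (stage in stages) {
    seed <- stage_seeds[[stage]]
    sdir <- file.path(out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    results[[stage]] <- switch(
      stage,
      spatial = run_stage_spatial(config$spatial, inputs, seed, sdir),
      cohort = run_stage_cohort(config$cohort, inputs, seed, sdir),
      microdissect = run_stage_microdissect(config$microdissect, inputs, seed, sdir)
    )
  }

  jsonlite::write_json(
    list(config = config, seed = config$seed,
         stage_seeds = as.list(stage_seeds),
         package_version = as.character(utils::packageVersion("spatsig")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null"
  )
  structure(invisible(out_dir), results = results)
}

run_stage_spatial <- function(params, inputs, seed, sdir) {
  params <- params %||% list()
  if (!is.null(inputs$cell_table)) {
    cells <- read_cell_table(inputs$cell_table)
  } else {
    cfg <- do.call(tissue_sim_config,
                   c(params$simulate %||% list(), list(seed = seed)))
    sim <- simulate_tissue(cfg)
    cells <- sim$cells
    write_cell_table(cells, file.path(sdir, "cells.csv"))
  }
  bw <- params$bandwidth_um %||% 50
  px <- params$pixel_um %||% 10
  thr <- params$threshold_quantile %||% 0.9
  min_area <- params$min_area_um2 %||% 10000
  immune <- params$immune_class %||% "IMMUNE_1"
  window <- params$window %||% c(min(cells$x_um), min(cells$y_um),
                                 max(cells$x_um), max(cells$y_um))
  out <- list()
  for (cls in c("TF_A", "TF_B")) {
    dm <- compute_density_map(cells, cls, bandwidth = bw, pixel_size = px,
                              window = window)
    hs <- derive_hotspots(dm, "quantile", thr, min_area, class_label = cls)
    write_density_map(dm, file.path(sdir, paste0("density_", cls, ".tsv")))
    write_hotspots_geojson(hs, file.path(sdir, paste0("hotspots_", cls, ".geojson")))
    out[[cls]] <- hs
  }
  pairs <- shortest_distance_pairs(cells, immune, out$TF_A, out$TF_B)
  utils::write.csv(pairs$per_cell, file.path(sdir, "immune_distances.csv"),
                   row.names = FALSE, quote = FALSE)
  list(hotspots = out, pairs = pairs)
}

run_stage_cohort <- function(params, inputs, seed, sdir) {
  params <- params %||% list()
  if (!is.null(inputs$expression)) {
    expr <- read_expression(inputs$expression)
    surv <- read_survival(inputs$survival)
    sig_genes <- read_gmt(inputs$signature)[[1L]]
  } else {
    cfg <- do.call(cohort_sim_config,
                   c(params$simulate %||% list(), list(seed = seed)))
    sim <- simulate_expression_cohort(cfg)
    expr <- sim$expr
    surv <- sim$survival
    sig_genes <- sim$signature_genes
    utils::write.csv(surv, file.path(sdir, "survival.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  scores <- gsva_scores(expr, sig_genes,
                        tau = params$tau %||% 1,
                        kcdf = params$kcdf %||% "gaussian")
  strat <- stratify_quartiles(scores)
  utils::write.csv(strat$assignment, file.path(sdir, "stratification.csv"),
                   row.names = FALSE, quote = FALSE)
  idx <- match(surv$sample_id, strat$assignment$sample_id)
  grp <- strat$assignment$group[idx]
  keep <- grp %in% c("lower", "upper")
  cox <- cox_hr(surv[keep, ], droplevels(grp[keep]), reference = "lower")
  lr <- logrank_test(surv[keep, ], droplevels(grp[keep]))
  jsonlite::write_json(
    list(hr = cox$hr, ci_low = cox$ci_low, ci_high = cox$ci_high,
         p_wald = cox$p_wald, logrank_chi2 = lr$chi2, logrank_p = lr$p),
    file.path(sdir, "cox.json"), auto_unbox = TRUE, digits = NA
  )
  list(scores = scores, stratification = strat, cox = cox)
}

run_stage_microdissect <- function(params, inputs, seed, sdir) {
  params <- params %||% list()
  if (!is.null(inputs$pairs)) {
    pairs <- read_alignment_pairs(inputs$pairs)
  } else {
    cfg <- do.call(read_sim_config,
                   c(params$simulate %||% list(), list(seed = seed)))
    pairs <- simulate_dual_species_reads(cfg)$pairs
  }
  lab <- assign_species(pairs, margin = params$margin %||% 0)
  counts <- compartment_counts(pairs, lab)
  utils::write.table(
    data.frame(gene = names(counts$graft), count = counts$graft),
    file.path(sdir, "graft_counts.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  utils::write.table(
    data.frame(gene = names(counts$host), count = counts$host),
    file.path(sdir, "host_counts.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  jsonlite::write_json(
    list(n_reads = counts$n_reads, n_graft = sum(counts$graft),
         n_host = sum(counts$host), n_unassigned = counts$n_unassigned),
    file.path(sdir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
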