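# End-to-end driver: simulate -> prep -> fit -> project -> metrics ->
# richness -> report, with a manifest recording every output file, its
# md5, and the seeds in play. All randomness flows from config$seed.

#' Build and validate a pipeline configuration
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` degrees.
#' @param resolution cell size in degrees.
#' @param n_species number of virtual species to simulate.
#' @param n_records_range min/max records per species (drawn uniformly).
#' @param n_covariates climate layers.
#' @param warming warming table ([default_warming_table()]).
#' @param periods,scenarios future periods and scenarios to project onto
#'   (defaults: all 4 x 4; the current grid is always included).
#' @param min_records occurrence filter (strictly more than this).
#' @param n_folds,auc_cutoff ensemble evaluation settings.
#' @param stability_band AOH change stability band (relative).
#' @param occupancy_cutoff virtual-species true-range threshold.
#' @param learner_kinds learners to fit (default all five).
#' @param sector_bands sector definition ([arctic_sectors()]).
#' @param seed master integer seed; per-stage seeds derive from it.
#' @param write_maps also write per-map suitability CSVs (large; default
#'   FALSE writes the manifest and summary tables only).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(extent = c(-40, 40, 50, 70), resolution = 1,
                            n_species = 20, n_records_range = c(30, 120),
                            n_covariates = 4,
                            warming = default_warming_table(),
                            periods = FUTURE_PERIODS,
                            scenarios = SSP_SCENARIOS,
                            min_records = 25, n_folds = 5, auc_cutoff = 0.7,
                            stability_band = 0.05, occupancy_cutoff = 0.5,
                            learner_kinds = LEARNER_KINDS,
                            sector_bands = arctic_sectors(),
                            seed = 1, write_maps = FALSE) {
  stopifnot(all(periods %in% FUTURE_PERIODS), all(scenarios %in% SSP_SCENARIOS))
  check_warming_table(warming)
  structure(list(extent = extent, resolution = resolution,
                 n_species = n_species, n_records_range = n_records_range,
                 n_covariates = n_covariates, warming = warming,
                 periods = periods, scenarios = scenarios,
                 min_records = min_records, n_folds = n_folds,
                 auc_cutoff = auc_cutoff, stability_band = stability_band,
                 occupancy_cutoff = occupancy_cutoff,
                 learner_kinds = learner_kinds, sector_bands = sector_bands,
                 seed = as.integer(seed), write_maps = write_maps),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes simulate, prep, fit, project, metrics, richness, and report on
#' a synthetic world, writing CSV/JSON outputs plus a manifest (file, md5,
#' stage) to `out_dir`. A rerun with the same config is bit-identical for
#' all deterministic outputs. Species for which no learner clears the AUC
#' cutoff are flagged unmodelable, logged, and excluded downstream.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param quiet suppress progress messages.
#' @return invisibly, a list: `coverage` report, `manifest` data.frame,
#'   `map_manifest` (one row per projected map), `changes` (full change
#'   table), `sector_reports`, `unmodelable` species ids, and `paths`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0); stages <- character(0)
  note <- function(path, stage) {
    files <<- c(files, path); stages <<- c(stages, stage); path
  }

  # --- simulate -------------------------------------------------------
  say("[simulate] climate matrix + %d virtual species", config$n_species)
  grids <- generate_climate(config$extent, config$resolution,
                            config$n_covariates, config$warming,
                            seed = config$seed)
  current <- grids[[1L]]
  keep <- vapply(grids, function(g)
    g$period == "current" ||
      (g$period %in% config$periods && g$scenario %in% config$scenarios), TRUE)
  grids <- grids[keep]
  vsp <- generate_virtual_species(current, config$n_species,
                                  occupancy_cutoff = config$occupancy_cutoff,
                                  seed = config$seed + 1L)
  occ <- fc_with_seed(config$seed + 2L, {
    n_rec <- sample(config$n_records_range[1]:config$n_records_range[2],
                    config$n_species, replace = TRUE)
    seeds <- sample.int(.Machine$integer.max %/% 2L, config$n_species)
    lapply(seq_along(vsp), function(i)
      sample_occurrences(vsp[[i]], current, n_rec[i], seed = seeds[i],
                         genus = sprintf("genus%02d", (i - 1L) %/% 5L + 1L),
                         family = sprintf("family%02d", (i - 1L) %/% 10L + 1L)))
  })
  note(write_occurrences(occ, file.path(out_dir, "occurrences.csv")), "simulate")
  grid_dir <- file.path(out_dir, "climate")
  dir.create(grid_dir, showWarnings = FALSE)
  for (g in grids) {
    p <- file.path(grid_dir, sprintf("climate__%s__%s", g$period, g$scenario))
    write_climate_grid(g, p)
    note(paste0(p, ".csv"), "simulate"); note(paste0(p, ".json"), "simulate")
  }

  # --- prep -----------------------------------------------------------
  filt <- filter_min_occurrences(occ, config$min_records)
  say("[prep] %d/%d species pass the >%d-record filter",
      filt$report$n_species_retained, filt$report$n_species_total,
      config$min_records)
  note(write_coverage_report(filt$report, file.path(out_dir, "coverage.json")),
       "prep")

  # --- fit + project --------------------------------------------------
  unmodelable <- character(0)
  map_rows <- list(); change_rows <- list(); maps_by_ps <- list()
  model_rows <- list()
  for (i in seq_along(filt$retained)) {
    o <- filt$retained[[i]]
    em <- tryCatch({
      ds <- build_modeling_dataset(o, current, seed = config$seed + 100L + i)
      fit_species_ensemble(ds, kinds = config$learner_kinds,
                           n_folds = config$n_folds,
                           auc_cutoff = config$auc_cutoff,
                           seed = config$seed + 200L + i)
    }, fc_unmodelable = function(e) NULL)
    if (is.null(em)) {
      say("[fit] %s: unmodelable (no learner >= AUC %.2f)", o$species_id,
          config$auc_cutoff)
      unmodelable <- c(unmodelable, o$species_id)
      next
    }
    model_rows[[length(model_rows) + 1L]] <- data.frame(
      species_id = em$species_id, threshold_tss = em$threshold_tss,
      t(em$weights))
    maps <- project_species(em, grids)
    for (m in maps) {
      key <- paste(m$period, m$scenario, sep = "__")
      maps_by_ps[[key]] <- c(maps_by_ps[[key]], list(m))
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        species_id = m$species_id, period = m$period, scenario = m$scenario,
        aoh_km2 = m$aoh_km2,
        extrapolation_fraction = attr(m, "extrapolation_fraction"))
    }
    change_rows[[length(change_rows) + 1L]] <-
      change_summary(maps, config$stability_band)
  }
  map_manifest <- do.call(rbind, map_rows)
  changes <- do.call(rbind, change_rows)
  say("[project] %d maps for %d modelled species",
      nrow(map_manifest), length(filt$retained) - length(unmodelable))
  p <- file.path(out_dir, "map_manifest.csv")
  utils::write.csv(map_manifest, p, row.names = FALSE); note(p, "project")
  p <- file.path(out_dir, "models.csv")
  utils::write.csv(do.call(rbind, model_rows), p, row.names = FALSE)
  note(p, "fit")
  p <- file.path(out_dir, "change_summary.csv")
  utils::write.csv(changes, p, row.names = FALSE); note(p, "metrics")

  # --- richness + report ----------------------------------------------
  rich <- lapply(maps_by_ps, stack_richness)
  rich_rows <- lapply(names(rich), function(k)
    data.frame(period = rich[[k]]$period, scenario = rich[[k]]$scenario,
               msr_spgc = round_half_up(mean_species_richness(rich[[k]]), 1)))
  p <- file.path(out_dir, "msr.csv")
  utils::write.csv(do.call(rbind, rich_rows), p, row.names = FALSE)
  note(p, "richness")
  cur_key <- "current__none"
  sector_reports <- list()
  for (k in setdiff(names(rich), cur_key)) {
    ps <- strsplit(k, "__", fixed = TRUE)[[1L]]
    sub <- changes[changes$period == ps[1L] & changes$scenario == ps[2L], ,
                   drop = FALSE]
    sector_reports[[k]] <- sector_summary(sub, rich[[k]], current,
                                          config$sector_bands)
  }
  if (length(sector_reports)) {
    p <- file.path(out_dir, "sector_report.csv")
    utils::write.csv(do.call(rbind, c(sector_reports,
                                      list(make.row.names = FALSE))),
                     p, row.names = FALSE)
    note(p, "report")
    p <- file.path(out_dir, "sector_report.json")
    jsonlite::write_json(sector_reports, p, dataframe = "rows", digits = NA)
    note(p, "report")
  }

  # --- manifest -------------------------------------------------------
  manifest <- data.frame(file = basename(files), stage = stages,
                         md5 = unname(tools::md5sum(files)))
  p <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, p, row.names = FALSE)
  jsonlite::write_json(list(seed = config$seed, n_species = config$n_species,
                            periods = config$periods,
                            scenarios = config$scenarios,
                            min_records = config$min_records,
                            auc_cutoff = config$auc_cutoff,
                            stability_band = config$stability_band),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  say("[done] %d files in %s", length(files) + 2L, out_dir)
  invisible(list(coverage = filt$report, manifest = manifest,
                 map_manifest = map_manifest, changes = changes,
                 richness = rich, sector_reports = sector_reports,
                 unmodelable = unmodelable, paths = files))
}
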