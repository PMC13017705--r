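# Ground-truth recovery experiment: the analysis-grade validation surface.
# A purely latitude-linear temperature world lets a warming increment be
# converted exactly into a known poleward shift of every species' true
# range, so the pipeline's recovered migration, discrimination, and AOH can
# be scored against exact truth.

#' Poleward-shift recovery experiment on virtual species
#'
#' Builds a noise-free world whose single covariate, temperature, is
#' strictly linear in latitude (lapse `lapse_per_deglat`), so the true
#' range of every species is exactly known and every construction below is
#' deterministic given the seed. A uniform warming increment of
#' `shift_deg * lapse_per_deglat` degrees C then shifts every species' true
#' range poleward by exactly `shift_deg` degrees of latitude. For each of
#' `n_species` temperature-limited virtual species the full pipeline is
#' run: biased presence sampling, thinning, background sampling, the
#' five-learner cross-validated ensemble, max-TSS binarization, projection
#' onto the current and shifted climates, and centroid migration. Species
#' optima are drawn from an interior quantile window so no true range
#' touches the grid edge before or after the shift.
#'
#' @param n_species number of virtual species; default 50.
#' @param n_presence occurrence records per species; default 100.
#' @param shift_deg imposed true poleward shift in degrees latitude.
#' @param extent,resolution grid definition; default 40 x 80 cells.
#' @param lapse_per_deglat temperature lapse (degrees C per degree lat).
#' @param seed master integer seed.
#' @return data.frame with one row per species: estimated `dlat_est`
#'   (recovered shift), `auc_true` (ensemble AUC against the true current
#'   range), `aoh_est_km2` and `aoh_true_km2` (estimated vs true current
#'   AOH) and `aoh_rel_err`; the imposed shift is in attribute
#'   `shift_deg`. Unmodelable species (none at these settings) would carry
#'   NA rows.
#' @export
shift_recovery_experiment <- function(n_species = 50, n_presence = 100,
                                      shift_deg = 2,
                                      extent = c(-40, 40, 48, 88),
                                      resolution = 1,
                                      lapse_per_deglat = 0.45, seed = 1) {
  warm <- shift_deg * lapse_per_deglat
  grids <- generate_climate(extent, resolution, n_covariates = 1,
                            warming = matrix(warm, 4, 4),
                            lapse_per_deglat = lapse_per_deglat,
                            noise_sd = 0, future_noise_sd = 0,
                            seed = seed)
  cur <- grids[[1L]]
  fut <- grids[[length(grids)]]  # any future grid: constant warming table
  vsp <- generate_virtual_species(
    cur, n_species,
    response_param_distribution = list(active = "temperature",
                                       opt_quantiles = c(0.25, 0.72),
                                       tol_sd_range = c(0.25, 0.35)),
    occupancy_cutoff = 0.5, seed = seed + 1L)
  areas <- cell_areas_km2(cur)
  Xcur <- covariate_matrix(cur)
  seeds <- fc_with_seed(seed + 2L,
                        sample.int(.Machine$integer.max %/% 2L, n_species))
  rows <- lapply(seq_len(n_species), function(i) {
    v <- vsp[[i]]
    occ <- sample_occurrences(v, cur, n_presence, seed = seeds[i])
    ds <- build_modeling_dataset(occ, cur, seed = seeds[i] + 1L)
    em <- fit_species_ensemble(ds, seed = seeds[i] + 2L)
    maps <- project_species(em, list(cur, fut))
    dlat_est <- if (maps[[2L]]$aoh_km2 > 0 && maps[[1L]]$aoh_km2 > 0)
      migration_vector(range_centroid(maps[[1L]]),
                       range_centroid(maps[[2L]]))$dlat else NA_real_
    truth <- as.vector(v$range_true)
    suit <- predict_ensemble(em, Xcur)
    data.frame(species_id = v$species_id, dlat_est = dlat_est,
               auc_true = auc(suit[truth], suit[!truth]),
               aoh_est_km2 = maps[[1L]]$aoh_km2,
               aoh_true_km2 = sum(areas[truth]),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$aoh_rel_err <- abs(out$aoh_est_km2 - out$aoh_true_km2) / out$aoh_true_km2
  attr(out, "shift_deg") <- shift_deg
  out
}
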