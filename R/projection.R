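# Projection: evaluate a species' ensemble on every period/scenario grid,
# binarize with the single threshold fit on current-period data, and derive
# the area of habitat (AOH) from spherical cell areas.

#' Spherical area of a grid cell
#'
#' Area of a lon/lat cell by the spherical band formula
#' `R^2 * dlambda * (sin(phi2) - sin(phi1))` with `R` = [R_EARTH_KM],
#' `dlambda` the cell's longitudinal width in radians, and `phi1`/`phi2`
#' its latitude bounds.
#'
#' @param lat_center cell-centre latitude(s), degrees.
#' @param resolution cell height in degrees.
#' @param lon_resolution cell width in degrees; defaults to `resolution`.
#' @return area(s) in km2.
#' @export
cell_area_km2 <- function(lat_center, resolution, lon_resolution = resolution) {
  if (any(abs(lat_center) + resolution / 2 > 90 + 1e-9))
    fc_stop("fc_invalid_latitude", "cell extends beyond +/-90 latitude")
  phi1 <- deg2rad(lat_center - resolution / 2)
  phi2 <- deg2rad(lat_center + resolution / 2)
  R_EARTH_KM^2 * deg2rad(lon_resolution) * (sin(phi2) - sin(phi1))
}

#' Construct a range map
#'
#' @param species_id character id.
#' @param grid the [climate_grid()] the map lives on.
#' @param suitability suitability matrix in `[0,1]` on the grid.
#' @param threshold binarization threshold; occupancy is
#'   `suitability >= threshold`.
#' @return object of class `range_map` with fields `occupancy` (logical
#'   matrix) and `aoh_km2` (sum of spherical areas of occupied cells).
#' @export
range_map <- function(species_id, grid, suitability, threshold) {
  occupancy <- suitability >= threshold
  areas <- cell_areas_km2(grid)
  structure(list(species_id = species_id, period = grid$period,
                 scenario = grid$scenario, suitability = suitability,
                 occupancy = occupancy,
                 aoh_km2 = sum(areas[as.vector(occupancy)]),
                 lon = grid$lon, lat = grid$lat,
                 resolution = grid$resolution, threshold = threshold),
            class = "range_map")
}

#' @export
print.range_map <- function(x, ...) {
  cat(sprintf("<range_map> %s | %s/%s | AOH %.0f km2 (%d cells)\n",
              x$species_id, x$period, x$scenario, x$aoh_km2,
              sum(x$occupancy)))
  invisible(x)
}

#' Project a species ensemble onto a set of climate grids
#'
#' Produces one [range_map()] per grid (17 for the full current + 4x4
#' matrix). Covariates are clamped to the training min/max before
#' prediction; the fraction of clamped cells per map is recorded in the
#' `extrapolation_fraction` attribute of each map. The same max-TSS
#' threshold, fit on current-period data, binarizes every map so that
#' threshold drift cannot confound change metrics.
#'
#' @param em a fitted `ensemble_model` (see [fit_species_ensemble()]).
#' @param grids list of [climate_grid()] objects, each supplying all
#'   covariates the ensemble was trained on.
#' @return list of `range_map` objects, one per grid, in input order.
#' @export
project_species <- function(em, grids) {
  if (is.na(em$threshold_tss))
    fc_stop("fc_projection_error", "ensemble has no binarization threshold")
  lapply(grids, function(g) {
    X <- covariate_matrix(g, em$covariate_names)
    clamped <- rep(FALSE, nrow(X))
    if (!is.null(em$train_range)) {
      lo <- rep(em$train_range$min, each = nrow(X))
      hi <- rep(em$train_range$max, each = nrow(X))
      clamped <- rowSums(X < lo | X > hi) > 0
    }
    suit <- matrix(predict_ensemble(em, X, clamp = TRUE),
                   length(g$lat), length(g$lon))
    rm <- range_map(em$species_id, g, suit, em$threshold_tss)
    attr(rm, "extrapolation_fraction") <- mean(clamped)
    rm
  })
}
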