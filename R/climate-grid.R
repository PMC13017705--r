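# climate_grid: a regular lon/lat raster stack of climate covariates for one
# (period, scenario). Plate carree semantics: cell-centre registered, north-up
# storage with latitude ascending along rows; all areas computed spherically.

PERIODS <- c("current", "2030s", "2050s", "2070s", "2090s")
SCENARIOS <- c("none", "SSP1-2.6", "SSP2-4.5", "SSP3-7.0", "SSP5-8.5")

#' Construct a climate grid
#'
#' A `climate_grid` holds one or more named covariate layers on a shared
#' regular lon/lat grid, labelled with a period and an emission scenario.
#' Layers are matrices with `length(lat)` rows (latitude ascending) and
#' `length(lon)` columns. Cells are addressed by the linear (column-major)
#' index of those matrices throughout the package.
#'
#' @param lon,lat numeric vectors of cell-centre coordinates, strictly
#'   ascending and regularly spaced; longitudes in `[-180, 180)`.
#' @param covariates named list of numeric matrices, each
#'   `length(lat) x length(lon)`.
#' @param period one of `"current"`, `"2030s"`, `"2050s"`, `"2070s"`,
#'   `"2090s"`.
#' @param scenario one of `"none"` (current only), `"SSP1-2.6"`,
#'   `"SSP2-4.5"`, `"SSP3-7.0"`, `"SSP5-8.5"`.
#' @param resolution cell size in degrees (one value used for both axes).
#' @return an object of class `climate_grid`.
#' @export
climate_grid <- function(lon, lat, covariates, period = "current",
                         scenario = "none", resolution = NULL) {
  if (length(lon) < 1L || length(lat) < 1L)
    fc_stop("fc_invalid_extent", "grid has zero cells")
  if (is.null(resolution)) {
    resolution <- if (length(lat) > 1L) lat[2L] - lat[1L]
                  else if (length(lon) > 1L) lon[2L] - lon[1L] else 1
  }
  if (resolution <= 0) fc_stop("fc_invalid_config", "resolution must be > 0")
  check_regular <- function(x, nm) {
    if (length(x) > 1L) {
      d <- diff(x)
      if (any(d <= 0)) fc_stop("fc_invalid_config", "%s not strictly ascending", nm)
      if (max(abs(d - d[1L])) > 1e-8)
        fc_stop("fc_invalid_config", "%s centres not regularly spaced", nm)
    }
  }
  check_regular(lon, "lon"); check_regular(lat, "lat")
  if (any(lon < -180 | lon >= 180))
    fc_stop("fc_invalid_config", "longitudes must lie in [-180, 180)")
  if (!is.list(covariates) || is.null(names(covariates)) ||
      any(!nzchar(names(covariates))))
    fc_stop("fc_invalid_config", "covariates must be a named list of matrices")
  for (nm in names(covariates)) {
    m <- covariates[[nm]]
    if (!is.matrix(m) || nrow(m) != length(lat) || ncol(m) != length(lon))
      fc_stop("fc_invalid_config",
              "covariate '%s' is not a %d x %d matrix", nm, length(lat), length(lon))
  }
  period <- match.arg(period, PERIODS)
  scenario <- match.arg(scenario, SCENARIOS)
  if ((period == "current") != (scenario == "none"))
    fc_stop("fc_invalid_config",
            "period 'current' pairs with scenario 'none' and vice versa")
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat),
                 covariates = covariates, period = period,
                 scenario = scenario, resolution = as.numeric(resolution)),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d x %d cells @ %g deg | %s / %s | layers: %s\n",
              length(x$lat), length(x$lon), x$resolution, x$period, x$scenario,
              paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

n_cells <- function(grid) length(grid$lat) * length(grid$lon)

grid_extent <- function(grid) {
  h <- grid$resolution / 2
  c(lon_min = min(grid$lon) - h, lon_max = max(grid$lon) + h,
    lat_min = min(grid$lat) - h, lat_max = max(grid$lat) + h)
}

same_grid <- function(a, b, tol = 1e-8) {
  length(a$lon) == length(b$lon) && length(a$lat) == length(b$lat) &&
    max(abs(a$lon - b$lon)) <= tol && max(abs(a$lat - b$lat)) <= tol
}

#' Cell centres of a grid in linear-index order
#'
#' @param grid a [climate_grid()].
#' @return data.frame with columns `lon`, `lat`, one row per cell, ordered by
#'   the column-major linear index used everywhere in the package.
#' @export
cell_centers <- function(grid) {
  data.frame(lon = rep(grid$lon, each = length(grid$lat)),
             lat = rep(grid$lat, times = length(grid$lon)))
}

#' Map coordinates to grid cell indices
#'
#' Points outside the grid extent map to `NA`.
#'
#' @param grid a [climate_grid()].
#' @param lon,lat coordinate vectors in degrees.
#' @return integer vector of linear (column-major) cell indices.
#' @export
cell_index <- function(grid, lon, lat) {
  h <- grid$resolution / 2
  col <- findInterval(lon, c(grid$lon - h, max(grid$lon) + h),
                      rightmost.closed = TRUE)
  row <- findInterval(lat, c(grid$lat - h, max(grid$lat) + h),
                      rightmost.closed = TRUE)
  bad <- col < 1L | col > length(grid$lon) | row < 1L | row > length(grid$lat)
  idx <- (col - 1L) * length(grid$lat) + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Covariate matrix of a grid
#'
#' @param grid a [climate_grid()].
#' @param layers optional character vector selecting/ordering layers; an
#'   absent layer raises a projection error naming it.
#' @return numeric matrix, cells (linear order) x covariates.
#' @export
covariate_matrix <- function(grid, layers = NULL) {
  if (is.null(layers)) layers <- names(grid$covariates)
  missing <- setdiff(layers, names(grid$covariates))
  if (length(missing))
    fc_stop("fc_projection_error",
            "grid %s/%s is missing covariate layer(s): %s",
            grid$period, grid$scenario, paste(missing, collapse = ", "))
  X <- vapply(layers, function(nm) as.numeric(grid$covariates[[nm]]),
              numeric(n_cells(grid)))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L, dimnames = list(NULL, layers))
  X
}

#' Per-cell spherical areas of a grid
#'
#' @param grid a [climate_grid()].
#' @return numeric vector of km2 per cell in linear order.
#' @export
cell_areas_km2 <- function(grid) {
  per_lat <- cell_area_km2(grid$lat, grid$resolution)
  rep(per_lat, times = length(grid$lon))
}
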