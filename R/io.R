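# Plain-text serialization. No raster/GIS stack is assumed: grids travel as
# long-format CSV plus a JSON metadata sidecar, occurrences and tables as
# CSV, reports as JSON. Every writer has a reader and write -> read ->
# write is value-identical.

#' Write a climate grid to CSV + JSON sidecar
#'
#' `<prefix>.csv` holds one row per cell per covariate (`lon, lat,
#' covariate, value`); `<prefix>.json` holds period, scenario, resolution
#' and the axis definitions.
#'
#' @param grid a [climate_grid()].
#' @param prefix file path without extension.
#' @return invisibly, the two file paths.
#' @export
write_climate_grid <- function(grid, prefix) {
  cc <- cell_centers(grid)
  long <- do.call(rbind, lapply(names(grid$covariates), function(nm)
    data.frame(lon = cc$lon, lat = cc$lat, covariate = nm,
               value = as.vector(grid$covariates[[nm]]))))
  csv <- paste0(prefix, ".csv"); meta <- paste0(prefix, ".json")
  utils::write.csv(long, csv, row.names = FALSE)
  jsonlite::write_json(
    list(format_version = 1L, period = grid$period, scenario = grid$scenario,
         resolution = grid$resolution, lon = grid$lon, lat = grid$lat,
         covariates = names(grid$covariates)),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}

#' Read a climate grid written by [write_climate_grid()]
#'
#' @param prefix file path without extension.
#' @return a [climate_grid()].
#' @export
read_climate_grid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  long <- utils::read.csv(paste0(prefix, ".csv"))
  nlat <- length(meta$lat); nlon <- length(meta$lon)
  covs <- lapply(meta$covariates, function(nm) {
    v <- long$value[long$covariate == nm]
    matrix(v, nlat, nlon)
  })
  names(covs) <- meta$covariates
  climate_grid(meta$lon, meta$lat, covs, meta$period, meta$scenario,
               meta$resolution)
}

#' Write occurrence sets to a single CSV
#'
#' Columns `species, lon, lat` plus `genus, family` when any taxonomy is
#' present.
#'
#' @param sets list of [occurrence_set()]s.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_occurrences <- function(sets, file) {
  rows <- do.call(rbind, lapply(sets, function(s) {
    if (!nrow(s$records)) return(NULL)
    data.frame(species = s$species_id, lon = s$records$lon,
               lat = s$records$lat,
               genus = s$taxonomy$genus %||% NA_character_,
               family = s$taxonomy$family %||% NA_character_)
  }))
  if (is.null(rows))
    rows <- data.frame(species = character(0), lon = numeric(0),
                       lat = numeric(0), genus = character(0),
                       family = character(0))
  if (all(is.na(rows$genus)) && all(is.na(rows$family)))
    rows <- rows[, c("species", "lon", "lat")]
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read occurrence sets from CSV
#'
#' @param file CSV with columns `species, lon, lat` and optional
#'   `genus, family`.
#' @return list of [occurrence_set()]s, one per species, in first-seen
#'   order.
#' @export
read_occurrences <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  ids <- unique(d$species)
  lapply(ids, function(id) {
    rows <- d[d$species == id, , drop = FALSE]
    occurrence_set(id, data.frame(lon = rows$lon, lat = rows$lat),
                   genus = if ("genus" %in% names(rows)) rows$genus[1L] else NA_character_,
                   family = if ("family" %in% names(rows)) rows$family[1L] else NA_character_)
  })
}

#' Serialize a coverage report to JSON
#'
#' @param report a `coverage_report` from [filter_min_occurrences()].
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_coverage_report <- function(report, file) {
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
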