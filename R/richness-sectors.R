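# Stacked species richness, mean species richness (spgc), richness-change
# maps, and per-sector roll-ups over a longitudinal five-sector mask.

#' Default five-sector longitude bands
#'
#' Approximate longitudinal divisions of the circumpolar Arctic flora:
#' European Russia-West Siberia (ER-WSS), East Siberia (ESS), Beringia
#' (BS), Canada (CS) and North Atlantic (NAS). The published sector borders
#' are cartographic, not machine-readable, so these bands are stand-ins
#' and should be replaced by user-supplied bounds for real analyses. A band
#' with `lon_min > lon_max` wraps across the antimeridian.
#'
#' @return data.frame with columns `sector`, `lon_min`, `lon_max`.
#' @export
arctic_sectors <- function() {
  data.frame(sector = c("ER-WSS", "ESS", "BS", "CS", "NAS"),
             lon_min = c(30, 90, 160, -140, -60),
             lon_max = c(90, 160, -140, -60, 30),
             stringsAsFactors = FALSE)
}

#' Assign longitudes to sectors
#'
#' @param lon numeric vector of longitudes in degrees.
#' @param sector_bands band table as in [arctic_sectors()]; bands are
#'   half-open `[lon_min, lon_max)` and may wrap the antimeridian.
#' @return character vector of sector labels (`NA` where no band matches).
#' @export
sector_of_lon <- function(lon, sector_bands = arctic_sectors()) {
  out <- rep(NA_character_, length(lon))
  lonw <- wrap_dlon(lon)  # normalize into (-180, 180]
  for (i in seq_len(nrow(sector_bands))) {
    a <- sector_bands$lon_min[i]; b <- sector_bands$lon_max[i]
    hit <- if (a < b) lonw >= a & lonw < b else lonw >= a | lonw < b
    out[hit & is.na(out)] <- sector_bands$sector[i]
  }
  out
}

#' Per-cell sector mask on a grid
#'
#' @param grid a [climate_grid()].
#' @param sector_bands band table as in [arctic_sectors()].
#' @return character matrix of sector labels on the grid.
#' @export
sector_mask <- function(grid, sector_bands = arctic_sectors()) {
  lab <- sector_of_lon(grid$lon, sector_bands)
  matrix(rep(lab, each = length(grid$lat)), length(grid$lat), length(grid$lon))
}

#' Stack binary range maps into a richness map
#'
#' @param maps list of [range_map()]s sharing one grid and one
#'   (period, scenario).
#' @return object of class `richness_map`: per-cell species counts plus
#'   grid/period metadata.
#' @export
stack_richness <- function(maps) {
  if (!length(maps)) fc_stop("fc_invalid_parameter", "no maps to stack")
  ref <- maps[[1L]]
  for (m in maps) {
    if (!identical(dim(m$occupancy), dim(ref$occupancy)) ||
        max(abs(m$lon - ref$lon)) > 1e-8 || max(abs(m$lat - ref$lat)) > 1e-8)
      fc_stop("fc_alignment_error", "range maps are not on a shared grid")
    if (m$period != ref$period || m$scenario != ref$scenario)
      fc_stop("fc_alignment_error", "range maps mix periods or scenarios")
  }
  counts <- Reduce(`+`, lapply(maps, function(m) m$occupancy * 1L))
  structure(list(counts = counts, period = ref$period,
                 scenario = ref$scenario, lon = ref$lon, lat = ref$lat,
                 resolution = ref$resolution, n_species = length(maps)),
            class = "richness_map")
}

#' Mean species richness (spgc)
#'
#' Unweighted arithmetic mean of per-cell species counts over the cells
#' selected by `mask` — "species per grid cell", deliberately not
#' area-weighted even though cell areas shrink poleward (set
#' `area_weighted = TRUE` for the weighted variant). Full precision is
#' returned; round at reporting time.
#'
#' @param rich a [stack_richness()] result.
#' @param mask optional logical matrix (or character matrix compared to
#'   `sector`) selecting cells; default all cells.
#' @param sector optional sector label when `mask` is a label matrix.
#' @param area_weighted weight cells by spherical area instead.
#' @return mean richness in species per grid cell.
#' @export
mean_species_richness <- function(rich, mask = NULL, sector = NULL,
                                  area_weighted = FALSE) {
  sel <- if (is.null(mask)) rep(TRUE, length(rich$counts))
         else if (is.character(mask)) !is.na(mask) & mask == sector
         else as.vector(mask)
  if (!any(sel)) fc_stop("fc_empty_mask", "mask selects no cells")
  x <- as.vector(rich$counts)[sel]
  if (!area_weighted) return(mean(x))
  grid_stub <- list(lon = rich$lon, lat = rich$lat, resolution = rich$resolution)
  w <- cell_areas_km2(grid_stub)[sel]
  sum(w * x) / sum(w)
}

#' Richness change map
#'
#' @param rich_future,rich_current [stack_richness()] results on the same
#'   grid.
#' @return matrix of per-cell differences (future - current) with an
#'   attribute `summary`: area-weighted fractions of cells gaining,
#'   losing, and unchanged.
#' @export
richness_change <- function(rich_future, rich_current) {
  if (!identical(dim(rich_future$counts), dim(rich_current$counts)) ||
      max(abs(rich_future$lon - rich_current$lon)) > 1e-8 ||
      max(abs(rich_future$lat - rich_current$lat)) > 1e-8)
    fc_stop("fc_alignment_error", "richness maps are not on a shared grid")
  d <- rich_future$counts - rich_current$counts
  grid_stub <- list(lon = rich_current$lon, lat = rich_current$lat,
                    resolution = rich_current$resolution)
  w <- cell_areas_km2(grid_stub)
  dv <- as.vector(d)
  attr(d, "summary") <- c(frac_gaining = sum(w[dv > 0]) / sum(w),
                          frac_losing = sum(w[dv < 0]) / sum(w),
                          frac_unchanged = sum(w[dv == 0]) / sum(w))
  d
}

#' Per-sector report for one period x scenario
#'
#' For each sector: species counts by change class (species assigned by
#' current centroid), extinction count, mean AOH fold change, MSR over the
#' sector's cells, and the mean migration vector. Species can occupy
#' several sectors' cells, but each is *assigned* to the single sector
#' holding its current centroid, so class counts across sectors sum to the
#' number of assigned species, while MSR uses all cells of the sector.
#'
#' @param summaries a [change_summary()] table restricted to one
#'   period x scenario.
#' @param rich the matching [stack_richness()] result.
#' @param grid the shared [climate_grid()].
#' @param sector_bands band table as in [arctic_sectors()].
#' @return data.frame, one row per sector present in the bands table.
#' @export
sector_summary <- function(summaries, rich, grid,
                           sector_bands = arctic_sectors()) {
  mask <- sector_mask(grid, sector_bands)
  rows <- lapply(sector_bands$sector, function(sc) {
    sec <- sector_of_lon(summaries$centroid_now_lon, sector_bands)
    sp <- summaries[!is.na(sec) & sec == sc, , drop = FALSE]
    mig <- suppressWarnings(sector_mean_migration(summaries, sector_bands, sc))
    msr <- if (any(!is.na(mask) & mask == sc))
      mean_species_richness(rich, mask = mask, sector = sc) else NA_real_
    data.frame(sector = sc, period = rich$period, scenario = rich$scenario,
               n_species = nrow(sp),
               n_expansion = sum(sp$change_class == "expansion", na.rm = TRUE),
               n_contraction = sum(sp$change_class == "contraction", na.rm = TRUE),
               n_stable = sum(sp$change_class == "stable", na.rm = TRUE),
               n_extinct = sum(sp$extinct_flag),
               mean_fold_change = if (nrow(sp)) mean(sp$fold_change, na.rm = TRUE)
                                  else NA_real_,
               msr_spgc = round_half_up(msr, 1),
               mean_dlat = mig$mean_dlat, mean_dlon = mig$mean_dlon,
               mean_shift_km = mig$mean_shift_km,
               pct_northward = mig$pct_northward,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
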