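# Per-species change metrics: AOH change class with a +/-5% stability band,
# fold change, extinction flags, and distributional-centroid migration
# vectors (spherical, antimeridian-safe).

#' Classify AOH change with a stability band
#'
#' Relative change is measured against the current AOH: species whose
#' absolute AOH change is within `stability_band` (default 5%) are
#' `"stable"`; otherwise the sign of the change gives `"expansion"` or
#' `"contraction"`. A zero current AOH has no defined baseline and yields
#' `NA` with a warning; such species are reported separately, not in class
#' counts.
#'
#' @param aoh_now,aoh_future AOH in km2 (vectors recycle).
#' @param stability_band relative half-width of the stable class; 0.05
#'   means changes of at most 5% of the current AOH count as stable.
#' @return character vector in `{expansion, contraction, stable}` (or NA).
#' @export
classify_change <- function(aoh_now, aoh_future, stability_band = 0.05) {
  if (any(aoh_now < 0 | aoh_future < 0))
    fc_stop("fc_invalid_parameter", "AOH must be nonnegative")
  n <- max(length(aoh_now), length(aoh_future))
  aoh_now <- rep_len(aoh_now, n); aoh_future <- rep_len(aoh_future, n)
  out <- rep(NA_character_, n)
  ok <- aoh_now > 0
  if (any(!ok))
    fc_warn("fc_undefined_baseline",
            "%d species with zero current AOH excluded from change classes",
            sum(!ok))
  rel <- (aoh_future[ok] - aoh_now[ok]) / aoh_now[ok]
  out[ok] <- ifelse(abs(rel) <= stability_band, "stable",
                    ifelse(rel > 0, "expansion", "contraction"))
  out
}

#' Distributional centroid of a range map
#'
#' Area-weighted spherical mean of the occupied cells: cell-centre unit
#' vectors are averaged with spherical cell-area weights, re-normalized,
#' and converted back to (lon, lat). Safe across the antimeridian.
#'
#' @param rm a [range_map()] with non-empty occupancy.
#' @return named numeric `c(lon, lat)` in degrees.
#' @export
range_centroid <- function(rm) {
  occ <- which(rm$occupancy)
  if (!length(occ))
    fc_stop("fc_no_centroid", "species %s: empty occupancy (extinct)",
            rm$species_id)
  nlat <- length(rm$lat)
  lat <- rm$lat[(occ - 1L) %% nlat + 1L]
  lon <- rm$lon[(occ - 1L) %/% nlat + 1L]
  w <- cell_area_km2(lat, rm$resolution)
  w <- w / sum(w)
  phi <- deg2rad(lat); lam <- deg2rad(lon)
  x <- sum(w * cos(phi) * cos(lam))
  y <- sum(w * cos(phi) * sin(lam))
  z <- sum(w * sin(phi))
  nrm <- sqrt(x^2 + y^2 + z^2)
  if (nrm < 1e-12)
    fc_stop("fc_no_centroid", "degenerate centroid (antipodal mass)")
  c(lon = rad2deg(atan2(y, x)), lat = rad2deg(asin(z / nrm)))
}

#' Migration vector between two centroids
#'
#' @param centroid_now,centroid_future named `c(lon, lat)` in degrees.
#' @return list with `dlat` (degrees, positive = northward), `dlon`
#'   (degrees, wrapped to `(-180, 180]`), `shift_km` (haversine great-
#'   circle distance), and `direction_class` (`"northward"` iff
#'   `dlat > 0`, else `"southward"` — exact zero counts as southward so the
#'   northward percentage is conservative).
#' @export
migration_vector <- function(centroid_now, centroid_future) {
  dlat <- unname(centroid_future["lat"] - centroid_now["lat"])
  dlon <- unname(wrap_dlon(centroid_future["lon"] - centroid_now["lon"]))
  list(dlat = dlat, dlon = dlon,
       shift_km = unname(haversine_km(
         centroid_now["lon"], centroid_now["lat"],
         centroid_future["lon"], centroid_future["lat"])),
       direction_class = if (dlat > 0) "northward" else "southward")
}

#' Per-species change summary across the projection matrix
#'
#' Builds the species x (period, scenario) change table from a list of
#' range maps containing one current map and any number of future maps:
#' AOH now/future, delta, fold change `(future - now)/now`, change class,
#' extinction flag (`aoh_future == 0`, the "nowhere-to-go" case), both
#' centroids, and the migration vector. Extinct futures get `NA` centroids
#' and migration fields; a zero current AOH yields `NA` class and
#' centroid-based columns.
#'
#' @param maps list of [range_map()]s for one species (from
#'   [project_species()]); exactly one must be current-period.
#' @param stability_band passed to [classify_change()].
#' @return data.frame, one row per future map.
#' @export
change_summary <- function(maps, stability_band = 0.05) {
  is_cur <- vapply(maps, function(m) m$period == "current", TRUE)
  if (sum(is_cur) != 1L)
    fc_stop("fc_invalid_parameter", "need exactly one current-period map")
  cur <- maps[[which(is_cur)]]
  fut <- maps[!is_cur]
  c_now <- if (cur$aoh_km2 > 0) range_centroid(cur) else c(lon = NA_real_, lat = NA_real_)
  rows <- lapply(fut, function(m) {
    extinct <- m$aoh_km2 == 0
    cls <- if (cur$aoh_km2 > 0)
      suppressWarnings(classify_change(cur$aoh_km2, m$aoh_km2, stability_band))
    else NA_character_
    if (!extinct && !anyNA(c_now)) {
      c_fut <- range_centroid(m)
      mv <- migration_vector(c_now, c_fut)
    } else {
      c_fut <- c(lon = NA_real_, lat = NA_real_)
      mv <- list(dlat = NA_real_, dlon = NA_real_, shift_km = NA_real_,
                 direction_class = NA_character_)
    }
    data.frame(species_id = m$species_id, period = m$period,
               scenario = m$scenario, aoh_now_km2 = cur$aoh_km2,
               aoh_future_km2 = m$aoh_km2,
               delta_km2 = m$aoh_km2 - cur$aoh_km2,
               fold_change = if (cur$aoh_km2 > 0)
                 (m$aoh_km2 - cur$aoh_km2) / cur$aoh_km2 else NA_real_,
               change_class = cls, extinct_flag = extinct,
               centroid_now_lon = c_now[["lon"]], centroid_now_lat = c_now[["lat"]],
               centroid_future_lon = c_fut[["lon"]], centroid_future_lat = c_fut[["lat"]],
               dlat = mv$dlat, dlon = mv$dlon, shift_km = mv$shift_km,
               direction_class = mv$direction_class,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Mean migration over one sector
#'
#' Species are assigned to a sector by their current centroid (longitude-
#' band membership). Means are unweighted over species with defined
#' migration vectors; longitudinal means use circular (vector) averaging
#' because sectors can span the antimeridian. Extinct species are excluded
#' from the means but counted in `n_extinct`.
#'
#' @param summaries a [change_summary()] table (typically restricted to
#'   one period x scenario) for many species.
#' @param sector_bands longitude-band table (see [arctic_sectors()]).
#' @param sector_id sector label to summarize.
#' @return list with `n`, `mean_dlat`, `mean_dlon`, `mean_shift_km`,
#'   `pct_northward`, `n_extinct`.
#' @export
sector_mean_migration <- function(summaries, sector_bands, sector_id) {
  sec <- sector_of_lon(summaries$centroid_now_lon, sector_bands)
  rows <- summaries[!is.na(sec) & sec == sector_id, , drop = FALSE]
  if (!nrow(rows)) {
    fc_warn("fc_empty_sector", "no species assigned to sector %s", sector_id)
    return(list(n = 0L, mean_dlat = NA_real_, mean_dlon = NA_real_,
                mean_shift_km = NA_real_, pct_northward = NA_real_,
                n_extinct = 0L))
  }
  ok <- !is.na(rows$dlat)
  mv <- rows[ok, , drop = FALSE]
  circ_mean <- function(deg) {
    r <- deg2rad(deg)
    rad2deg(atan2(mean(sin(r)), mean(cos(r))))
  }
  list(n = sum(ok),
       mean_dlat = if (any(ok)) mean(mv$dlat) else NA_real_,
       mean_dlon = if (any(ok)) circ_mean(mv$dlon) else NA_real_,
       mean_shift_km = if (any(ok)) mean(mv$shift_km) else NA_real_,
       pct_northward = if (any(ok)) 100 * mean(mv$dlat > 0) else NA_real_,
       n_extinct = sum(rows$extinct_flag))
}
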