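# Shared helpers: conditions, seeded evaluation, rounding, spherical geometry.

#' Mean Earth radius in kilometres
#'
#' IUGG mean radius used for all spherical areas and distances.
#' @export
R_EARTH_KM <- 6371.0088

fc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "floracast_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

fc_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "floracast_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so no function leaks hidden global randomness.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
fc_with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Half-up rounding to `digits` decimals (base round() is round-half-even).
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Wrap a longitude difference into (-180, 180]
#'
#' @param dlon numeric vector of longitude differences in degrees.
#' @return wrapped differences; +2 not -358 across the antimeridian.
#' @export
wrap_dlon <- function(dlon) {
  d <- dlon %% 360
  ifelse(d > 180, d - 360, d)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Great-circle distance (haversine)
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance in km on a sphere of radius [R_EARTH_KM].
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dphi <- p2 - p1
  dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * R_EARTH_KM * asin(sqrt(a))
}
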