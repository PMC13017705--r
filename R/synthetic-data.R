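# Virtual-world generator: climate grids for the 1 + 4x4 period/scenario
# matrix, virtual species with Gaussian climate responses and known true
# ranges, and spatially biased presence-only samples. Everything downstream
# can therefore be validated against exact ground truth.

FUTURE_PERIODS <- PERIODS[-1L]
SSP_SCENARIOS <- SCENARIOS[-1L]

#' Default end-of-century warming table
#'
#' Spatial-mean warming increments (degrees C relative to current) for the
#' four future periods (rows) by four emission scenarios (columns). The
#' 2090s row spans 2.8 C (SSP1-2.6) to 10.4 C (SSP5-8.5), the projected
#' end-of-century Arctic surface warming range across those scenarios;
#' earlier decades are interpolated so increments are nondecreasing in both
#' period and emission level.
#'
#' @return 4 x 4 numeric matrix with dimnames `periods x scenarios`.
#' @export
default_warming_table <- function() {
  m <- rbind(
    "2030s" = c(1.0, 1.2, 1.3, 1.5),
    "2050s" = c(1.8, 2.3, 2.8, 3.4),
    "2070s" = c(2.4, 3.5, 5.0, 6.6),
    "2090s" = c(2.8, 4.5, 7.4, 10.4))
  colnames(m) <- SSP_SCENARIOS
  m
}

check_warming_table <- function(w) {
  if (!is.matrix(w) || !identical(dim(w), c(4L, 4L)))
    fc_stop("fc_invalid_config", "warming table must be 4 periods x 4 scenarios")
  if (is.null(rownames(w))) rownames(w) <- FUTURE_PERIODS
  if (is.null(colnames(w))) colnames(w) <- SSP_SCENARIOS
  w <- w[FUTURE_PERIODS, SSP_SCENARIOS, drop = FALSE]
  if (any(w < 0)) fc_stop("fc_invalid_config", "warming increments must be >= 0")
  if (any(apply(w, 2, diff) < 0))
    fc_stop("fc_invalid_config", "warming must be nondecreasing across periods")
  if (any(apply(w, 1, diff) < 0))
    fc_stop("fc_invalid_config", "warming must be nondecreasing across scenarios")
  w
}

# Smooth Gaussian random field: white noise smoothed by a separable
# Gaussian weight matrix (row-normalized, so any grid size works), then
# rescaled to the requested marginal sd. Cheap and spatially realistic
# enough for testing.
gaussian_field <- function(nrow, ncol, corr_cells = 5, sd = 1) {
  if (sd <= 0) return(matrix(0, nrow, ncol))
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (corr_cells > 0) {
    smooth_w <- function(n) {
      W <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = corr_cells)
      W / rowSums(W)
    }
    z <- smooth_w(nrow) %*% z %*% t(smooth_w(ncol))
  }
  s <- stats::sd(z)
  if (is.finite(s) && s > 0) z <- z * (sd / s)
  z - mean(z)
}

#' Generate the current + 16 future climate grids
#'
#' Builds one current grid plus all 4 period x 4 scenario future grids (17
#' in total, matching the per-species map count of the projection matrix).
#' The temperature-like layer of the current grid decreases linearly with
#' latitude (poleward cooling) plus a smooth random field; each future grid
#' is the current grid with the scenario/period warming increment added to
#' the temperature layer, plus smooth spatially correlated noise of
#' amplitude `future_noise_sd`. Non-temperature layers are carried through
#' unchanged by default so ground truth stays interpretable.
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)` in degrees.
#' @param resolution cell size in degrees; must be > 0.
#' @param n_covariates number of layers (>= 1). Layer 1 is `temperature`
#'   (degrees C, latitudinal gradient), layer 2 `precipitation` (mm,
#'   longitudinal gradient), further layers `cov3`, `cov4`, ... are
#'   independent smooth fields.
#' @param warming warming table as in [default_warming_table()]:
#'   nonnegative, nondecreasing in period and in emission level.
#' @param lapse_per_deglat temperature decrease per degree latitude
#'   (degrees C); default 0.45.
#' @param noise_sd marginal sd of the smooth field added to the current
#'   temperature layer (degrees C).
#' @param future_noise_sd marginal sd of the smooth noise added to each
#'   future temperature layer on top of its increment.
#' @param corr_cells correlation length of the random fields, in cells.
#' @param seed integer seed; identical seeds give bit-identical grids.
#' @return list of 17 [climate_grid()] objects; first element is current.
#' @export
generate_climate <- function(extent = c(-180, 180, 48, 84), resolution = 1,
                             n_covariates = 4,
                             warming = default_warming_table(),
                             lapse_per_deglat = 0.45,
                             noise_sd = 1, future_noise_sd = 0.3,
                             corr_cells = 5, seed = 1) {
  if (resolution <= 0) fc_stop("fc_invalid_config", "resolution must be > 0")
  warming <- check_warming_table(warming)
  lon_n <- floor((extent[2] - extent[1]) / resolution + 1e-9)
  lat_n <- floor((extent[4] - extent[3]) / resolution + 1e-9)
  if (lon_n < 1 || lat_n < 1)
    fc_stop("fc_invalid_extent", "extent contains zero cells")
  lon <- extent[1] + (seq_len(lon_n) - 0.5) * resolution
  lat <- extent[3] + (seq_len(lat_n) - 0.5) * resolution
  if (n_covariates < 1) fc_stop("fc_invalid_config", "need >= 1 covariate")

  fc_with_seed(seed, {
    lat_m <- matrix(lat, lat_n, lon_n)
    lon_m <- matrix(lon, lat_n, lon_n, byrow = TRUE)
    covs <- list(temperature = 20 - lapse_per_deglat * lat_m +
                   gaussian_field(lat_n, lon_n, corr_cells, noise_sd))
    if (n_covariates >= 2)
      covs$precipitation <- pmax(
        400 + 150 * sin(deg2rad(lon_m)) +
          gaussian_field(lat_n, lon_n, corr_cells, 60), 0)
    if (n_covariates >= 3)
      for (j in 3:n_covariates)
        covs[[paste0("cov", j)]] <- gaussian_field(lat_n, lon_n, corr_cells, 1)

    grids <- list(climate_grid(lon, lat, covs, "current", "none", resolution))
    for (p in FUTURE_PERIODS) for (s in SSP_SCENARIOS) {
      fc <- covs
      fc$temperature <- covs$temperature + warming[p, s] +
        gaussian_field(lat_n, lon_n, corr_cells, future_noise_sd)
      grids[[length(grids) + 1L]] <- climate_grid(lon, lat, fc, p, s, resolution)
    }
    grids
  })
}

#' Construct a virtual species
#'
#' @param species_id character id.
#' @param response_params data.frame with columns `covariate`, `opt`, `tol`
#'   (tol may be `Inf` for a covariate the species ignores).
#' @param suitability_true matrix in `[0,1]` on the grid.
#' @param occupancy_cutoff threshold in (0,1) defining the true range.
#' @return object of class `virtual_species` with `range_true` a logical
#'   matrix (`suitability_true >= occupancy_cutoff`).
#' @export
virtual_species <- function(species_id, response_params, suitability_true,
                            occupancy_cutoff = 0.5) {
  if (occupancy_cutoff <= 0 || occupancy_cutoff >= 1)
    fc_stop("fc_invalid_parameter", "occupancy_cutoff must be in (0,1)")
  if (any(suitability_true < 0 | suitability_true > 1))
    fc_stop("fc_invalid_parameter", "suitability_true must lie in [0,1]")
  structure(list(species_id = species_id, response_params = response_params,
                 suitability_true = suitability_true,
                 range_true = suitability_true >= occupancy_cutoff,
                 occupancy_cutoff = occupancy_cutoff),
            class = "virtual_species")
}

#' Evaluate a Gaussian response surface on a grid
#'
#' Suitability is the product over covariates of
#' `exp(-(x - opt)^2 / (2 tol^2))`; `tol = Inf` contributes a factor of 1.
#'
#' @param grid a [climate_grid()].
#' @param response_params data.frame (`covariate`, `opt`, `tol`).
#' @return suitability matrix in `[0,1]` on the grid.
#' @export
gaussian_suitability <- function(grid, response_params) {
  if (any(response_params$tol <= 0))
    fc_stop("fc_invalid_parameter", "response tolerance must be > 0")
  suit <- matrix(1, length(grid$lat), length(grid$lon))
  for (i in seq_len(nrow(response_params))) {
    nm <- response_params$covariate[i]
    tol <- response_params$tol[i]
    if (!is.finite(tol)) next
    x <- grid$covariates[[nm]]
    if (is.null(x)) fc_stop("fc_projection_error", "missing covariate '%s'", nm)
    suit <- suit * exp(-(x - response_params$opt[i])^2 / (2 * tol^2))
  }
  suit
}

#' Generate virtual species on a current climate grid
#'
#' Each species gets a Gaussian response per covariate: the optimum is the
#' covariate value at a random quantile of its current distribution, the
#' tolerance a random multiple of the covariate's spatial sd. Suitability is
#' the product of the per-covariate responses; the true range thresholds it
#' at `occupancy_cutoff`.
#'
#' @param climate_current the current-period [climate_grid()].
#' @param n_species number of species (>= 1).
#' @param response_param_distribution list with `opt_quantiles = c(lo, hi)`
#'   (quantile window the optima are drawn from), `tol_sd_range = c(lo, hi)`
#'   (tolerance as a multiple of the covariate sd), and optionally `active`,
#'   a character vector of covariates the species respond to (others get
#'   `tol = Inf`).
#' @param occupancy_cutoff true-range threshold in (0,1); default 0.5.
#' @param seed integer seed.
#' @return list of [virtual_species()] objects.
#' @export
generate_virtual_species <- function(climate_current, n_species,
                                     response_param_distribution = list(),
                                     occupancy_cutoff = 0.5, seed = 1) {
  if (n_species < 1) fc_stop("fc_invalid_parameter", "n_species must be >= 1")
  if (occupancy_cutoff <= 0 || occupancy_cutoff >= 1)
    fc_stop("fc_invalid_parameter", "occupancy_cutoff must be in (0,1)")
  d <- utils::modifyList(
    list(opt_quantiles = c(0.2, 0.8), tol_sd_range = c(0.75, 1.5),
         active = names(climate_current$covariates)),
    response_param_distribution)
  if (any(d$tol_sd_range <= 0))
    fc_stop("fc_invalid_parameter", "tolerance range must be > 0")
  covs <- names(climate_current$covariates)
  sds <- vapply(climate_current$covariates, stats::sd, 0)
  draw_params <- function() data.frame(
    covariate = covs,
    opt = vapply(covs, function(nm)
      stats::quantile(climate_current$covariates[[nm]],
                      stats::runif(1, d$opt_quantiles[1], d$opt_quantiles[2]),
                      names = FALSE), 0),
    tol = ifelse(covs %in% d$active,
                 pmax(sds, 1e-8) *
                   stats::runif(length(covs), d$tol_sd_range[1], d$tol_sd_range[2]),
                 Inf),
    row.names = NULL)
  fc_with_seed(seed, {
    lapply(seq_len(n_species), function(i) {
      # a virtual species must have a non-empty true range to serve as
      # ground truth: redraw response params until the cutoff is reached
      for (try in 1:100) {
        rp <- draw_params()
        suit <- gaussian_suitability(climate_current, rp)
        if (any(suit >= occupancy_cutoff)) break
        if (try == 100)
          fc_stop("fc_no_habitat",
                  "could not draw a species with a non-empty range; widen tol_sd_range or lower occupancy_cutoff")
      }
      virtual_species(sprintf("vsp%03d", i), rp, suit, occupancy_cutoff)
    })
  })
}

#' Construct an occurrence set
#'
#' @param species_id character id.
#' @param records data.frame with columns `lon`, `lat` (no NAs).
#' @param genus,family optional taxonomy.
#' @return object of class `occurrence_set`.
#' @export
occurrence_set <- function(species_id, records, genus = NA_character_,
                           family = NA_character_) {
  records <- as.data.frame(records)
  if (nrow(records) && (anyNA(records$lon) || anyNA(records$lat)))
    fc_stop("fc_invalid_parameter", "occurrence coordinates contain NA")
  structure(list(species_id = species_id,
                 records = records[, c("lon", "lat"), drop = FALSE],
                 taxonomy = list(genus = genus, family = family)),
            class = "occurrence_set")
}

#' Sample biased presence-only occurrences for a virtual species
#'
#' Records are drawn (with replacement) from the species' occupied cells
#' with probability proportional to `suitability_true * bias_field`, then
#' jittered uniformly within the cell, strictly inside its bounds.
#'
#' @param vsp a [virtual_species()].
#' @param grid the [climate_grid()] the species was built on.
#' @param n_records number of records (>= 0).
#' @param bias_field optional nonnegative matrix on the grid (uniform if
#'   omitted), emulating e.g. accessibility bias in herbarium sampling.
#' @param seed integer seed.
#' @param genus,family optional taxonomy passed through.
#' @return an [occurrence_set()].
#' @export
sample_occurrences <- function(vsp, grid, n_records, bias_field = NULL,
                               seed = 1, genus = NA_character_,
                               family = NA_character_) {
  if (n_records < 0) fc_stop("fc_invalid_parameter", "n_records must be >= 0")
  occ <- which(vsp$range_true)
  if (n_records == 0)
    return(occurrence_set(vsp$species_id,
                          data.frame(lon = numeric(0), lat = numeric(0)),
                          genus, family))
  if (!length(occ))
    fc_stop("fc_no_habitat", "species %s has an empty true range", vsp$species_id)
  w <- vsp$suitability_true[occ]
  if (!is.null(bias_field)) {
    if (any(bias_field < 0))
      fc_stop("fc_invalid_parameter", "bias_field must be nonnegative")
    w <- w * bias_field[occ]
  }
  if (sum(w) <= 0)
    fc_stop("fc_no_habitat", "bias field removes all habitat for %s",
            vsp$species_id)
  nlat <- length(grid$lat)
  half <- grid$resolution / 2
  fc_with_seed(seed, {
    cells <- occ[sample.int(length(occ), n_records, replace = TRUE, prob = w)]
    row <- (cells - 1L) %% nlat + 1L
    col <- (cells - 1L) %/% nlat + 1L
    jit <- function(n) stats::runif(n, -0.999 * half, 0.999 * half)
    occurrence_set(vsp$species_id,
                   data.frame(lon = grid$lon[col] + jit(n_records),
                              lat = grid$lat[row] + jit(n_records)),
                   genus, family)
  })
}
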