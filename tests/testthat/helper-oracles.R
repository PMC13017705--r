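# Independent oracles and tiny fixture builders. Oracles deliberately use
# brute-force formulations so they share no code path with the package.

# Pair-count AUC: mean over presence x background pairs of 1/0.5/0.
auc_pairs_oracle <- function(sp, sb) {
  tot <- 0
  for (p in sp) for (b in sb)
    tot <- tot + if (p > b) 1 else if (p == b) 0.5 else 0
  tot / (length(sp) * length(sb))
}

# Exhaustive max-TSS scan over the same candidate set definition.
tss_oracle <- function(sp, sb) {
  u <- sort(unique(c(sp, sb)))
  cand <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  tss <- sapply(cand, function(t) mean(sp >= t) + mean(sb < t) - 1)
  list(threshold = cand[which(tss >= max(tss) - 1e-12)[1]], max_tss = max(tss),
       candidates = cand, tss = tss)
}

# Brute-force richness: loop over species, then over cells.
richness_brute_oracle <- function(occ_list) {
  out <- matrix(0L, nrow(occ_list[[1]]), ncol(occ_list[[1]]))
  for (o in occ_list)
    for (i in seq_len(nrow(o))) for (j in seq_len(ncol(o)))
      out[i, j] <- out[i, j] + as.integer(o[i, j])
  out
}

# Planar-free spherical mean of points (unit-vector average), used to check
# centroids numerically.
spherical_mean_oracle <- function(lon, lat, w = rep(1, length(lon))) {
  w <- w / sum(w)
  phi <- lat * pi / 180; lam <- lon * pi / 180
  x <- sum(w * cos(phi) * cos(lam)); y <- sum(w * cos(phi) * sin(lam))
  z <- sum(w * sin(phi))
  c(lon = atan2(y, x) * 180 / pi,
    lat = asin(z / sqrt(x^2 + y^2 + z^2)) * 180 / pi)
}

# Small grid with arbitrary covariate layers.
make_grid <- function(lon = seq(-4.5, 4.5, by = 1),
                      lat = seq(50.5, 59.5, by = 1),
                      covs = NULL, period = "current", scenario = "none") {
  if (is.null(covs)) {
    lat_m <- matrix(lat, length(lat), length(lon))
    covs <- list(temperature = 20 - 0.45 * lat_m)
  }
  climate_grid(lon, lat, covs, period, scenario, resolution = 1)
}

# Range map straight from a logical occupancy matrix.
make_rm <- function(occ, grid, species = "sp1") {
  range_map(species, grid, occ * 1, threshold = 0.5)
}

# A strictly separable modelling dataset: presence and background values
# drawn from disjoint supports of one covariate.
make_separable_dataset <- function(n_presence = 40, n_background = 60,
                                   seed = 1, gap = 6) {
  withr::with_seed(seed, {
    Xp <- cbind(temperature = runif(n_presence, gap, gap + 2))
    Xb <- cbind(temperature = runif(n_background, 0, 2))
  })
  structure(list(species_id = "sep", presence_cells = seq_len(n_presence),
                 background_cells = n_presence + seq_len(n_background),
                 X_presence = Xp, X_background = Xb,
                 covariate_names = "temperature"),
            class = "modeling_dataset")
}
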