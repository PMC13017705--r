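# synthetic world: climate matrix, virtual species, occurrence sampling

test_that("generate_climate returns the 1 + 4x4 projection matrix", {
  grids <- generate_climate(extent = c(-10, 10, 50, 60), resolution = 1,
                            seed = 1)
  expect_length(grids, 17L)
  expect_equal(grids[[1]]$period, "current")
  expect_equal(grids[[1]]$scenario, "none")
  combos <- t(vapply(grids[-1], function(g) c(g$period, g$scenario),
                     character(2)))
  expect_equal(nrow(unique(combos)), 16L)
  expect_setequal(unique(combos[, 1]), c("2030s", "2050s", "2070s", "2090s"))
  expect_setequal(unique(combos[, 2]),
                  c("SSP1-2.6", "SSP2-4.5", "SSP3-7.0", "SSP5-8.5"))
})

test_that("climate generation is deterministic and additive in warming", {
  a <- generate_climate(extent = c(0, 10, 50, 60), seed = 42)
  b <- generate_climate(extent = c(0, 10, 50, 60), seed = 42)
  expect_identical(a, b)

  # zero warming, zero noise -> future identical to current
  z <- generate_climate(extent = c(0, 10, 50, 60), warming = matrix(0, 4, 4),
                        future_noise_sd = 0, seed = 7)
  expect_identical(z[[2]]$covariates$temperature,
                   z[[1]]$covariates$temperature)

  # stated increments, no noise -> exact mean difference
  w <- matrix(0, 4, 4, dimnames = list(c("2030s", "2050s", "2070s", "2090s"),
                                       c("SSP1-2.6", "SSP2-4.5", "SSP3-7.0",
                                         "SSP5-8.5")))
  w["2030s", ] <- 1; w[c("2050s", "2070s", "2090s"), ] <- 4
  g <- generate_climate(extent = c(0, 10, 50, 60), warming = w,
                        future_noise_sd = 0, seed = 7)
  g90 <- Filter(function(x) x$period == "2090s" && x$scenario == "SSP1-2.6", g)[[1]]
  expect_equal(mean(g90$covariates$temperature -
                    g[[1]]$covariates$temperature), 4.0, tolerance = 1e-12)
})

test_that("current temperature decreases poleward; warming is monotone", {
  grids <- generate_climate(extent = c(-20, 20, 50, 70), seed = 3)
  cur <- grids[[1]]
  prof <- rowMeans(cur$covariates$temperature)
  expect_lt(cor(prof, cur$lat) , -0.95)  # dominated by the lapse

  mt <- vapply(grids[-1], function(g)
    mean(g$covariates$temperature), 0)
  per <- vapply(grids[-1], function(g) g$period, "")
  sc <- vapply(grids[-1], function(g) g$scenario, "")
  for (p in unique(per))
    expect_true(all(diff(mt[per == p][order(match(sc[per == p],
      c("SSP1-2.6", "SSP2-4.5", "SSP3-7.0", "SSP5-8.5")))]) >= -1e-9))
  for (s in unique(sc))
    expect_true(all(diff(mt[sc == s][order(match(per[sc == s],
      c("2030s", "2050s", "2070s", "2090s")))]) >= -1e-9))
})

test_that("invalid configs error with typed conditions", {
  bad <- matrix(c(2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1), 4, 4)
  expect_error(generate_climate(warming = bad), class = "fc_invalid_config")
  expect_error(generate_climate(extent = c(0, 0, 50, 60)),
               class = "fc_invalid_extent")
  expect_error(generate_climate(resolution = 0), class = "fc_invalid_config")
})

test_that("Gaussian response matches its closed form and thresholds cleanly", {
  g <- make_grid(lon = 0, lat = c(50.5, 51.5),
                 covs = list(temperature = matrix(c(0, 1), 2, 1)))
  rp <- data.frame(covariate = "temperature", opt = 0, tol = 1)
  suit <- gaussian_suitability(g, rp)
  expect_equal(suit[1, 1], 1.0)               # at the optimum
  expect_equal(suit[2, 1], exp(-0.5), tolerance = 1e-12)

  v <- virtual_species("s", rp, suit, occupancy_cutoff = 0.99)
  expect_equal(sum(v$range_true), 1L)
  v2 <- virtual_species("s", rp, suit * 0.5, occupancy_cutoff = 0.99)
  expect_equal(sum(v2$range_true), 0L)        # flat low -> empty range

  expect_error(gaussian_suitability(g, data.frame(covariate = "temperature",
                                                  opt = 0, tol = 0)),
               class = "fc_invalid_parameter")
})

test_that("generated virtual species satisfy their invariants", {
  cur <- generate_climate(extent = c(-20, 20, 50, 70), seed = 5)[[1]]
  vsp <- generate_virtual_species(cur, 8, seed = 9)
  expect_length(vsp, 8L)
  for (v in vsp) {
    expect_true(all(v$suitability_true >= 0 & v$suitability_true <= 1))
    expect_true(all(v$suitability_true[v$range_true] > 0))
    expect_true(all(v$suitability_true[v$range_true] >= v$occupancy_cutoff))
  }
  expect_identical(generate_virtual_species(cur, 3, seed = 9),
                   generate_virtual_species(cur, 3, seed = 9))
})

test_that("occurrence sampling respects support, bias, and seeds", {
  g <- make_grid()
  suit <- matrix(0, 10, 10)
  suit[5, 5] <- 1
  v <- virtual_species("one", data.frame(), suit)
  expect_equal(nrow(sample_occurrences(v, g, 0, seed = 1)$records), 0L)

  o <- sample_occurrences(v, g, 30, seed = 1)
  expect_true(all(abs(o$records$lon - g$lon[5]) < 0.5))
  expect_true(all(abs(o$records$lat - g$lat[5]) < 0.5))

  # two cells 0.9 vs 0.1: multinomial oracle, 3 binomial s.e.
  suit2 <- matrix(0, 10, 10); suit2[3, 3] <- 0.9; suit2[8, 8] <- 0.1
  v2 <- virtual_species("two", data.frame(), suit2, occupancy_cutoff = 0.05)
  o2 <- sample_occurrences(v2, g, 10000, seed = 2)
  frac <- mean(abs(o2$records$lat - g$lat[3]) < 0.5)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))

  # all samples inside true-range cells
  idx <- cell_index(g, o2$records$lon, o2$records$lat)
  expect_true(all(v2$range_true[idx]))

  expect_identical(sample_occurrences(v2, g, 50, seed = 4),
                   sample_occurrences(v2, g, 50, seed = 4))

  v0 <- virtual_species("none", data.frame(), matrix(0, 10, 10))
  expect_error(sample_occurrences(v0, g, 5), class = "fc_no_habitat")
})
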