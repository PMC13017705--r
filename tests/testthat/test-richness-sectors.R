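# stacked richness, MSR, richness change, sector partitioning

test_that("stacked richness equals the brute-force species loop", {
  g <- make_grid()

  occ <- matrix(FALSE, 10, 10); occ[4, 4] <- TRUE
  maps3 <- lapply(1:3, function(i) make_rm(occ, g, paste0("sp", i)))
  rich <- stack_richness(maps3)
  expect_equal(rich$counts[4, 4], 3L)
  expect_equal(sum(rich$counts), 3L)

  withr::with_seed(31, {
    occs <- lapply(1:10, function(i) matrix(runif(100) < 0.3, 10, 10))
  })
  maps <- lapply(seq_along(occs), function(i)
    make_rm(occs[[i]], g, paste0("sp", i)))
  rich10 <- stack_richness(maps)
  expect_equal(rich10$counts, richness_brute_oracle(occs))

  # conservation: total richness == total occupied cells over species
  expect_equal(sum(rich10$counts), sum(vapply(occs, sum, 0L)))

  # monotonicity: adding a species never decreases any cell
  rich11 <- stack_richness(c(maps, list(make_rm(occs[[1]], g, "sp11"))))
  expect_true(all(rich11$counts >= rich10$counts))

  # mixed grids or periods refuse to stack
  g2 <- make_grid(lon = seq(-4.5, 4.5, 1), lat = seq(60.5, 69.5, 1))
  expect_error(stack_richness(list(maps[[1]], make_rm(occs[[2]], g2))),
               class = "fc_alignment_error")
})

test_that("MSR is the plain per-cell mean over the mask", {
  g <- make_grid()
  uni <- stack_richness(lapply(1:5, function(i)
    make_rm(matrix(TRUE, 10, 10), g, paste0("sp", i))))
  expect_equal(mean_species_richness(uni), 5.0)

  two <- list(counts = matrix(c(0L, 10L), 1, 2), period = "current",
              scenario = "none", lon = c(0.5, 1.5), lat = 50.5,
              resolution = 1, n_species = 10L)
  class(two) <- "richness_map"
  expect_equal(mean_species_richness(two), 5.0)

  # sector-restricted MSR equals an independent recount from the table
  withr::with_seed(32, {
    occs <- lapply(1:6, function(i) matrix(runif(100) < 0.4, 10, 10))
  })
  rich <- stack_richness(lapply(seq_along(occs), function(i)
    make_rm(occs[[i]], g, paste0("sp", i))))
  bands <- data.frame(sector = c("W", "E"), lon_min = c(-180, 0),
                      lon_max = c(0, 180))
  mask <- sector_mask(g, bands)
  recount <- mean(as.vector(rich$counts)[as.vector(mask == "W")])
  expect_equal(mean_species_richness(rich, mask = mask, sector = "W"),
               recount)

  expect_error(mean_species_richness(rich, mask = matrix(FALSE, 10, 10)),
               class = "fc_empty_mask")
})

test_that("richness change maps difference, direction, and additivity", {
  g <- make_grid()
  mk_rich <- function(counts) {
    structure(list(counts = counts, period = "current", scenario = "none",
                   lon = g$lon, lat = g$lat, resolution = 1,
                   n_species = max(counts)), class = "richness_map")
  }
  a <- mk_rich(matrix(2L, 10, 10))
  expect_true(all(richness_change(a, a) == 0))

  # one species expanding north (top rows gain) and contracting south
  cur <- matrix(0L, 10, 10); cur[2:5, ] <- 1L
  fut <- matrix(0L, 10, 10); fut[4:8, ] <- 1L
  d <- richness_change(mk_rich(fut), mk_rich(cur))
  expect_true(all(d[6:8, ] > 0))   # northern rows gain (lat ascends with row)
  expect_true(all(d[2:3, ] < 0))   # southern rows lose
  s <- attr(d, "summary")
  expect_equal(unname(sum(s)), 1, tolerance = 1e-12)

  # additivity: (A->B) + (B->C) == (A->C)
  b <- mk_rich(matrix(3L, 10, 10)); c3 <- mk_rich(matrix(7L, 10, 10))
  lhs <- richness_change(b, a) + richness_change(c3, b)
  rhs <- richness_change(c3, a)
  expect_equal(unclass(lhs), unclass(rhs), ignore_attr = TRUE)
})

test_that("sector partition identity holds for MSR", {
  g <- make_grid(lon = seq(-179.5, 179.5, 1), lat = seq(60.5, 64.5, 1))
  withr::with_seed(33, {
    occs <- lapply(1:7, function(i) matrix(runif(5 * 360) < 0.3, 5, 360))
  })
  rich <- stack_richness(lapply(seq_along(occs), function(i)
    make_rm(occs[[i]], g, paste0("sp", i))))
  bands <- arctic_sectors()
  mask <- sector_mask(g, bands)
  msrs <- vapply(bands$sector, function(sc)
    mean_species_richness(rich, mask = mask, sector = sc), 0)
  ncells <- vapply(bands$sector, function(sc) sum(mask == sc), 0L)
  expect_equal(sum(msrs * ncells) / sum(ncells),
               mean_species_richness(rich), tolerance = 1e-12)
  expect_equal(sum(ncells), length(mask))  # bands partition the extent
})

test_that("sector summaries isolate change to the right sector", {
  g <- make_grid(lon = seq(0.5, 39.5, 1), lat = seq(50.5, 59.5, 1))
  bands <- data.frame(sector = c("A", "B"), lon_min = c(0, 20),
                      lon_max = c(20, 40))
  # species 1 lives in A and contracts hard; species 2 lives in B, stays put
  occA_now <- matrix(FALSE, 10, 40); occA_now[3:6, 2:12] <- TRUE
  occA_fut <- matrix(FALSE, 10, 40); occA_fut[5:6, 2:12] <- TRUE
  occB <- matrix(FALSE, 10, 40); occB[3:6, 25:35] <- TRUE

  mk_fut <- function(occ, id) {
    m <- make_rm(occ, g, id); m$period <- "2090s"; m$scenario <- "SSP5-8.5"; m
  }
  csA <- change_summary(list(make_rm(occA_now, g, "sp1"),
                             mk_fut(occA_fut, "sp1")))
  csB <- change_summary(list(make_rm(occB, g, "sp2"), mk_fut(occB, "sp2")))
  cs <- rbind(csA, csB)
  rich_fut <- stack_richness(list(mk_fut(occA_fut, "sp1"),
                                  mk_fut(occB, "sp2")))
  rep <- sector_summary(cs, rich_fut, g, bands)

  a <- rep[rep$sector == "A", ]; b <- rep[rep$sector == "B", ]
  expect_equal(a$n_contraction, 1L)
  expect_equal(b$n_contraction, 0L)
  expect_equal(b$n_stable, 1L)
  expect_equal(b$mean_shift_km, 0)
  expect_equal(b$pct_northward, 0)  # zero shift counts as not-northward

  # single-band mask reproduces the whole-region numbers
  one <- sector_summary(cs, rich_fut, g,
                        data.frame(sector = "ALL", lon_min = 0, lon_max = 40))
  expect_equal(one$n_species, 2L)
  expect_equal(one$n_contraction, 1L)
  msr_full <- mean_species_richness(rich_fut)
  expect_equal(one$msr_spgc, floor(10 * msr_full + 0.5 + 1e-9) / 10)
})
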