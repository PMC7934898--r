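test_that("probability grids are normalised and follow the latitudinal weights", {
  m <- make_band_mask(4L)
  for (type in c("flat", "unimodal", "bimodal")) {
    pg <- build_probability_grid(m, type)
    expect_equal(sum(pg$weight), 1, tolerance = 1e-12)
    expect_true(all(pg$weight >= 0))
  }
  # flat: equal weight at equal |latitude|
  pg <- build_probability_grid(m, "flat")
  w_n <- pg$weight[pg$lat == 45.5][1]
  w_s <- pg$weight[pg$lat == -45.5][1]
  expect_equal(w_n, w_s, tolerance = 1e-12)
  # unimodal: weight ratio between cells matches the closed form
  pg_u <- build_probability_grid(m, "unimodal")
  w0 <- pg_u$weight[pg_u$lat == 0.5][1]
  w60 <- pg_u$weight[pg_u$lat == 60.5][1]
  oracle <- (exp(-0.5^2 / 800) * cos(0.5 * pi / 180)) /
    (exp(-60.5^2 / 800) * cos(60.5 * pi / 180))
  expect_equal(w0 / w60, oracle, tolerance = 1e-10)
  # bimodal: temperate cells outweigh equatorial and polar ones
  pg_b <- build_probability_grid(m, "bimodal")
  expect_gt(pg_b$weight[pg_b$lat == 45.5][1],
            pg_b$weight[pg_b$lat == 0.5][1])
  expect_gt(pg_b$weight[pg_b$lat == 45.5][1],
            pg_b$weight[pg_b$lat == 80.5][1])
})

test_that("species attributes respect the truncated decay distribution", {
  expect_error(decay_params(rate = 0), "decay rate")
  expect_error(decay_params(rate = -1), "decay rate")
  set.seed(1)
  attrs <- draw_species_attributes(1000)
  expect_equal(nrow(attrs), 1000L)
  expect_true(all(attrs$n_occurrences >= 1 & attrs$n_occurrences <= 300))
  expect_true(all(attrs$range_extent >= 100 & attrs$range_extent <= 15000))
  # monotone decay: frequency of 1 occurrence exceeds that of 10, and the
  # empirical ratio tracks the analytic pmf
  set.seed(2)
  big <- draw_species_attributes(1e5)
  f1 <- mean(big$n_occurrences == 1)
  f10 <- mean(big$n_occurrences == 10)
  expect_gt(f1, f10)
  pmf <- lbgwin:::occurrence_count_pmf(decay_params())
  expect_equal(f1 / f10, pmf[1] / pmf[10], tolerance = 0.1)
  expect_equal(f1, pmf[1], tolerance = 0.05)
})

test_that("occurrence placement honours the range extent", {
  # pin the initial point to a known cell so the audit radius is known
  seed_mask <- shallow_mask_from_cells(91L, 181L)  # centre (0.5, 0.5)
  pg <- build_probability_grid(seed_mask, "flat")
  big_mask <- make_band_mask(10L)
  set.seed(7)
  rec <- place_species_occurrences(500, 40, pg, big_mask)
  expect_equal(nrow(rec), 40L)
  d <- oracle_km(0.5, 0.5, rec$lat, rec$lon)   # independent haversine
  expect_true(all(d <= 500))

  set.seed(8)
  one <- place_species_occurrences(500, 1, pg, big_mask)
  expect_equal(nrow(one), 1L)
  expect_lte(oracle_km(0.5, 0.5, one$lat, one$lon), 500)

  # degenerate support: a single-cell mask absorbs all occurrences
  set.seed(9)
  solo <- place_species_occurrences(10000, 25, pg, seed_mask)
  expect_true(all(solo$cell_row == 91L & solo$cell_col == 181L))
})

test_that("assemblages are reproducible and complete", {
  m <- make_band_mask(6L)
  occ1 <- simulate_assemblage("Asselian", m, "flat", n_species = 5,
                              n_replicates = 2, seed = 3)
  occ2 <- simulate_assemblage("Asselian", m, "flat", n_species = 5,
                              n_replicates = 2, seed = 3)
  expect_identical(occ1, occ2)
  for (r in 1:2)
    expect_equal(length(unique(occ1$species_id[occ1$replicate == r])), 5L)
  # all occurrences lie in mask cells, at their cell centres
  key <- paste(occ1$cell_row, occ1$cell_col)
  expect_true(all(key %in% paste(m$row, m$col)))
  ctr <- cell_center(occ1$cell_row, occ1$cell_col)
  expect_equal(occ1$lat, ctr$lat)
  expect_equal(occ1$lon, ctr$lon)
  # replicate subsets reproduce: replicate 1 alone equals replicate 1 of 2
  occ_one <- simulate_assemblage("Asselian", m, "flat", n_species = 5,
                                 n_replicates = 1, seed = 3)
  expect_identical(occ_one, occ1[occ1$replicate == 1, ])
})

test_that("species-area relationship: a bin with twice the cells is richer", {
  # [0,15)N has 20 columns of shelf, [15,30)N has 10, all else empty
  rows <- c(rep(91:105, each = 20), rep(106:120, each = 10))
  cols <- c(rep(171:190, times = 15), rep(171:180, times = 15))
  m <- shallow_mask_from_cells(rows, cols)
  occ <- simulate_assemblage("Asselian", m, "flat", n_species = 100,
                             n_replicates = 50, seed = 13)
  scheme <- lat_bin_scheme()
  rich <- sapply(1:50, function(r)
    as.numeric(bin_richness_curve(occ, scheme, r)))
  big_bin <- mean(rich[match("0_15N", scheme$label), ])
  small_bin <- mean(rich[match("15_30N", scheme$label), ])
  expect_gt(big_bin, small_bin)
})

test_that("unimodal and bimodal types peak in their zones on a uniform shelf", {
  m <- make_band_mask(8L)
  scheme <- lat_bin_scheme()
  mean_prop <- function(type) {
    occ <- simulate_assemblage("Asselian", m, type, n_species = 400,
                               n_replicates = 10, seed = 17)
    curves <- lapply(1:10, function(r) bin_richness_curve(occ, scheme, r))
    normalize_proportional(mean_curve(curves))
  }
  pk_u <- peak_location(mean_prop("unimodal"))
  expect_equal(pk_u$zone, "tropics")
  pk_b <- peak_location(mean_prop("bimodal"))
  expect_equal(pk_b$zone, "temperate")
})

test_that("flat gradients are hemispherically balanced on a uniform shelf", {
  # mirrored bins have equal shelf area; mean richness should agree to
  # well under 20% relative difference at this scale
  m <- make_band_mask(8L)
  scheme <- lat_bin_scheme()
  occ <- simulate_assemblage("Asselian", m, "flat", n_species = 1000,
                             n_replicates = 10, seed = 19)
  curves <- sapply(1:10, function(r)
    as.numeric(bin_richness_curve(occ, scheme, r)))
  mean_rich <- rowMeans(curves)
  for (b in 1:6) {
    north <- mean_rich[13 - b]; south <- mean_rich[b]
    expect_lt(abs(north - south) / max(north, south), 0.2)
  }
})

test_that("derived seeds stay in 32-bit integer range and separate streams", {
  s <- c(derive_seed(1, 0, 1, 1), derive_seed(1, 0, 1, 2),
         derive_seed(1, 0, 2, 1), derive_seed(2, 0, 1, 1),
         derive_seed(2^30, 55, 3, 100))
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(length(unique(s)), 5L)
  expect_identical(derive_seed(7, 3, 2, 1), derive_seed(7, 3, 2, 1))
})
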