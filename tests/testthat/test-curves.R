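test_that("binned richness counts distinct species, allowing multi-bin ranges", {
  occ <- make_occ(species_id = c(1, 1, 1, 2, 2),
                  lat = c(10, 10.5, 20, 10, -40),
                  lon = c(0, 1, 2, 3, 4))
  cv <- bin_richness_curve(occ)
  scheme <- lat_bin_scheme()
  # species 1 spans bins [0,15)N and [15,30)N; species 2 adds [0,15)N
  # and [45,30)S
  expect_equal(as.numeric(cv)[match("0_15N", scheme$label)], 2)
  expect_equal(as.numeric(cv)[match("15_30N", scheme$label)], 1)
  expect_equal(as.numeric(cv)[match("30_45S", scheme$label)], 1)
  expect_equal(sum(as.numeric(cv)), 4)
  # empty table: all-zero curve
  expect_equal(as.numeric(bin_richness_curve(occ[0, ])), rep(0, 12))
})

test_that("binned richness equals a brute-force distinct count on random tables", {
  set.seed(31)
  occ <- make_occ(species_id = sample(1:12, 100, replace = TRUE),
                  lat = runif(100, -89, 89), lon = runif(100, -179, 179))
  cv <- as.numeric(bin_richness_curve(occ))
  scheme <- lat_bin_scheme()
  for (b in 1:12) {
    inbin <- occ$lat >= scheme$lower[b] & occ$lat < scheme$upper[b]
    expect_equal(cv[b], length(unique(occ$species_id[inbin])))
  }
})

test_that("global richness is the distinct species count", {
  occ <- make_occ(c(1, 2, 2, 7), lat = c(0, 1, 2, 3), lon = 1:4)
  expect_equal(global_richness(occ), 3L)
  expect_equal(global_richness(occ[0, ]), 0L)
  set.seed(32)
  occ2 <- make_occ(sample(1:40, 150, replace = TRUE),
                   lat = runif(150, -80, 80), lon = runif(150, -170, 170))
  expect_equal(global_richness(occ2), length(unique(occ2$species_id)))
})

test_that("analytic rarefaction expectation matches enumeration and limits", {
  # full draw: both species always seen
  expect_equal(expected_rarefied_richness(c(A = 1, B = 1), 2), 2)
  # counts {A:2, B:2}, quota 2: enumeration over C(4,2) = 6 draws -> 5/3
  expect_equal(expected_rarefied_richness(c(2, 2), 2), 5 / 3,
               tolerance = 1e-12)
  # quota = N recovers the species count exactly
  expect_equal(expected_rarefied_richness(c(3, 1, 5), 9), 3)
  expect_error(expected_rarefied_richness(c(2, 2), 5), "exceeds")
  # cross-check against vegan's classical rarefaction
  cnt <- c(7, 3, 2, 1, 1)
  expect_equal(expected_rarefied_richness(cnt, 6),
               as.numeric(vegan::rarefy(cnt, 6)), tolerance = 1e-9)
})

test_that("bootstrap rarefaction agrees with the analytic expectation", {
  # below quota: insufficient data, missing (not zero)
  expect_true(is.na(rarefied_richness(rep(1, 30), quota = 50)))
  # monoculture: exactly one species in any draw
  set.seed(41)
  expect_equal(rarefied_richness(rep(7, 60), quota = 50, n_boot = 20), 1)
  # Monte-Carlo agreement within 3 standard errors on random fixtures
  set.seed(42)
  for (i in 1:5) {
    counts <- sample(1:8, sample(3:6, 1), replace = TRUE)
    pool <- rep(seq_along(counts), counts)
    quota <- sample(2:min(sum(counts), 6), 1)
    n_boot <- 4000
    draws <- vapply(seq_len(n_boot), function(j)
      length(unique(pool[sample.int(length(pool), quota)])), numeric(1))
    got <- rarefied_richness(pool, quota, n_boot)
    want <- expected_rarefied_richness(counts, quota)
    se <- sd(draws) / sqrt(n_boot)
    expect_lt(abs(got - want), 3 * se + 1e-9)
  }
})

test_that("rarefied expectation is monotone in quota and bounded by richness", {
  counts <- c(5, 4, 2, 1)
  vals <- vapply(1:12, function(q)
    expected_rarefied_richness(counts, q), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_lte(max(vals), length(counts))
})

test_that("rarefied curves mark sub-quota bins missing", {
  occ <- make_occ(species_id = c(rep(1:3, each = 4), 9),
                  lat = c(rep(5, 12), 40), lon = c(1:12, 1))
  set.seed(43)
  cv <- rarefied_curve(occ, quota = 10, n_boot = 50)
  scheme <- lat_bin_scheme()
  expect_false(is.na(as.numeric(cv)[match("0_15N", scheme$label)]))
  expect_true(is.na(as.numeric(cv)[match("30_45N", scheme$label)]))  # 1 occ
  expect_true(is.na(as.numeric(cv)[match("75_90S", scheme$label)]))  # empty
})

test_that("proportional normalisation rescales to unit sum and keeps missing bins", {
  c1 <- make_prop_curve(c(2, 2, rep(0, 10)))
  expect_equal(as.numeric(c1)[1:2], c(0.5, 0.5))
  expect_equal(sum(as.numeric(c1)), 1, tolerance = 1e-12)
  # single positive bin
  c2 <- make_prop_curve(c(rep(0, 7), 7, rep(0, 4)))
  expect_equal(as.numeric(c2)[8], 1)
  # missing bins stay missing, remaining mass renormalised
  raw <- lbgwin:::new_lbg_curve(c(3, NA, 1, rep(NA, 9)), "rarefied", "t")
  p <- normalize_proportional(raw)
  expect_equal(as.numeric(p)[c(1, 3)], c(0.75, 0.25))
  expect_true(all(is.na(as.numeric(p)[-c(1, 3)])))
  # all-zero curve degrades to all missing with a warning
  zero <- lbgwin:::new_lbg_curve(rep(0, 12), "raw", "t")
  expect_warning(pz <- normalize_proportional(zero), "no positive richness")
  expect_true(all(is.na(as.numeric(pz))))
})

test_that("replicate averaging is missing-aware and matches direct summation", {
  a <- lbgwin:::new_lbg_curve(c(4, NA, 2, rep(0, 9)), "rarefied", "t")
  b <- lbgwin:::new_lbg_curve(c(2, NA, NA, rep(0, 9)), "rarefied", "t")
  m <- mean_curve(list(a, b))
  expect_equal(as.numeric(m)[1], 3)       # mean of 4, 2
  expect_true(is.na(as.numeric(m)[2]))    # missing everywhere
  expect_equal(as.numeric(m)[3], 2)       # present in one replicate
  # identical curves average to themselves
  expect_equal(as.numeric(mean_curve(list(a, a))), as.numeric(a))
  # mixed kinds are rejected
  raw <- lbgwin:::new_lbg_curve(rep(1, 12), "raw", "t")
  expect_error(mean_curve(list(a, raw)), "mixed kinds")
  # brute-force mean over many random curves
  set.seed(44)
  curves <- lapply(1:100, function(i)
    lbgwin:::new_lbg_curve(runif(12), "raw", "t"))
  m100 <- mean_curve(curves)
  want <- colMeans(do.call(rbind, lapply(curves, as.numeric)))
  expect_equal(as.numeric(m100), unname(want), tolerance = 1e-12)
})
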