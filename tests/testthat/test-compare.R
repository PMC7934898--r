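test_that("total displacement spans [0, 2] with the documented endpoints", {
  u <- make_prop_curve(rep(1, 12))
  expect_equal(total_displacement(u, u), 0)
  a <- make_prop_curve(c(0, 1, rep(0, 10)))   # all mass in bin 2
  b <- make_prop_curve(c(rep(0, 8), 1, 0, 0, 0))  # all mass in bin 9
  expect_equal(total_displacement(a, b), 2)
  # half-overlapping supports: direct summation oracle
  c1 <- make_prop_curve(c(0.5, 0.5, rep(0, 10)))
  c2 <- make_prop_curve(c(0, 0.5, 0.5, rep(0, 9)))
  expect_equal(total_displacement(c1, c2), 1.0)
  # symmetry
  expect_equal(total_displacement(a, b), total_displacement(b, a))
  # non-proportional input is rejected
  raw <- lbgwin:::new_lbg_curve(1:12, "raw", "t")
  expect_error(total_displacement(raw, a), "proportional")
})

test_that("displacement re-normalises over jointly non-missing bins", {
  # curve with a missing bin: D stays within [0, 2] and identical
  # restrictions give 0
  full <- make_prop_curve(c(4, 3, 2, 1, rep(0, 8)))
  holed <- normalize_proportional(
    lbgwin:::new_lbg_curve(c(4, NA, 2, 1, rep(0, 8)), "rarefied", "t"))
  d <- total_displacement(full, holed)
  expect_gte(d, 0); expect_lte(d, 2)
  # oracle: renormalise both over the joint support by hand
  j <- c(1, 3:12)
  v1 <- as.numeric(full)[j] / sum(as.numeric(full)[j])
  v2 <- as.numeric(holed)[j] / sum(as.numeric(holed)[j])
  expect_equal(d, sum(abs(v1 - v2)), tolerance = 1e-12)
})

test_that("residuals subtract reference from test and sum to zero on full curves", {
  ref <- make_prop_curve(c(1, 2, 3, rep(1, 9)))
  expect_equal(unname(curve_residuals(ref, ref)), rep(0, 12))
  shifted <- as.numeric(ref); shifted[1] <- shifted[1] + 0.1
  shifted[2] <- shifted[2] - 0.1
  test <- lbgwin:::new_lbg_curve(shifted, "proportional", "t")
  res <- curve_residuals(test, ref)
  expect_equal(unname(res[1]), 0.1, tolerance = 1e-12)
  expect_equal(unname(res[2]), -0.1, tolerance = 1e-12)
  expect_equal(sum(res), 0, tolerance = 1e-12)
})

test_that("Pearson correlation matches the product-moment formula", {
  c1 <- make_prop_curve(c(1, 2, 3, 5, rep(1, 8)))
  c2 <- lbgwin:::new_lbg_curve(2 * as.numeric(c1), "proportional", "t")
  expect_equal(pearson_r(c1, c2)$r, 1, tolerance = 1e-12)
  c3 <- lbgwin:::new_lbg_curve(1 - as.numeric(c1), "proportional", "t")
  expect_equal(pearson_r(c1, c3)$r, -1, tolerance = 1e-12)
  # hand-computed product-moment value on a 4-point fixture
  x <- c(1, 2, 3, 5); y <- c(2, 4, 6, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  cx <- lbgwin:::new_lbg_curve(c(x, rep(NA, 8)), "rarefied", "t")
  cy <- lbgwin:::new_lbg_curve(c(y, rep(NA, 8)), "rarefied", "t")
  got <- pearson_r(cx, cy)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$n, 4L)
  # degenerate variance flags undefined instead of erroring
  flat1 <- lbgwin:::new_lbg_curve(rep(1, 12), "proportional", "t")
  out <- pearson_r(flat1, c1)
  expect_false(out$defined)
  expect_true(is.na(out$r))
})

test_that("KS statistic equals the brute-force EDF supremum", {
  expect_equal(ks_two_sample(1:5, 1:5)$ks_stat, 0)
  expect_equal(ks_two_sample(1:3, 11:13)$ks_stat, 1)
  x <- c(0.1, 0.2, 0.3); y <- c(0.2, 0.3, 0.4)
  got <- ks_two_sample(x, y)
  # brute-force EDF evaluation at all sample points
  pts <- sort(unique(c(x, y)))
  sup <- max(vapply(pts, function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
  expect_equal(got$ks_stat, sup)
  expect_equal(got$ks_stat, 1 / 3, tolerance = 1e-12)
  expect_error(ks_two_sample(numeric(), 1:3), "non-empty")
})

test_that("peak location breaks ties toward the tropics with North first", {
  scheme <- lat_bin_scheme()
  v <- rep(0, 12); v[match("30_45N", scheme$label)] <- 1
  pk <- peak_location(make_prop_curve(v))
  expect_equal(pk$bin_label, "30_45N")
  expect_equal(pk$zone, "temperate")
  expect_false(pk$tie)
  v2 <- rep(0, 12); v2[match("0_15S", scheme$label)] <- 1
  expect_equal(peak_location(make_prop_curve(v2))$zone, "tropics")
  # exact tie between 0_15N and 45_60N resolves to the tropical bin
  v3 <- rep(0, 12)
  v3[match(c("0_15N", "45_60N"), scheme$label)] <- 1
  pk3 <- peak_location(make_prop_curve(v3))
  expect_equal(pk3$bin_label, "0_15N")
  expect_true(pk3$tie)
  # at equal |lat|, North precedes South
  v4 <- rep(0, 12)
  v4[match(c("0_15N", "0_15S"), scheme$label)] <- 1
  expect_equal(peak_location(make_prop_curve(v4))$bin_label, "0_15N")
  all_na <- lbgwin:::new_lbg_curve(rep(NA_real_, 12), "rarefied", "t")
  expect_error(peak_location(all_na), "entirely missing")
})

test_that("coefficients of determination match squared hand-computed r", {
  x <- 1:10
  expect_equal(r_squared(x, 3 * x + 1)$r_squared, 1, tolerance = 1e-12)
  out_const <- r_squared(x, rep(2, 10))
  expect_false(out_const$defined)
  set.seed(51)
  y <- x + rnorm(10)
  expect_equal(r_squared(x, y)$r_squared, cor(x, y)^2, tolerance = 1e-12)
  # undefined pairs are dropped and counted
  y2 <- y; y2[3] <- NA
  out <- r_squared(x, y2)
  expect_equal(out$n_used, 9L)
  expect_equal(out$n_dropped, 1L)
})

test_that("rank-sum test matches exhaustive enumeration on small samples", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- rank_sum_test(a, b)
  expect_equal(got$statistic, 0)   # complete separation: U = 0 for a
  # enumerate all C(6,3) = 20 rank assignments for the exact two-sided p
  vals <- c(a, b)
  combos <- combn(6, 3)
  u_of <- function(idx) {
    ranks <- rank(vals)
    sum(ranks[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  u_all <- apply(combos, 2, u_of)
  u_obs <- u_of(1:3)
  p_exact <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))  # 4.5 = mean U
  expect_equal(got$p, p_exact, tolerance = 1e-12)
  # identical samples: no location shift, p near 1
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p, 0.99)
  # complete separation with n = 20 each hits the extreme statistic
  big <- rank_sum_test(1:20, 21:40)
  expect_equal(big$statistic, 0)
  expect_lt(big$p, 0.001)
})

test_that("compare_curves bundles the pairwise statistics coherently", {
  c1 <- make_prop_curve(c(1, 2, 5, 3, 1, rep(1, 7)))
  row_id <- compare_curves(c1, c1, "self")
  expect_equal(row_id$D, 0)
  expect_equal(row_id$ks_stat, 0)
  expect_equal(row_id$r, 1)
  expect_true(row_id$peak_zone_match)
  expect_equal(row_id$peak_bin_test, row_id$peak_bin_ref)
  expect_equal(row_id$n_bins_used, 12L)
})
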