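# Pairwise curve-comparison statistics: per-bin residuals, total
# displacement D, Pearson correlation, Kolmogorov-Smirnov two-sample
# tests, peak bin/zone detection, coefficients of determination against
# sampling metrics, and rank-sum contrasts of score series.

.joint_bins <- function(c1, c2) {
  which(!is.na(as.numeric(c1)) & !is.na(as.numeric(c2)))
}

.check_proportional <- function(...) {
  for (c in list(...)) {
    stopifnot(inherits(c, "lbg_curve"))
    if (curve_kind(c) != "proportional")
      stop("curve comparison requires proportional curves, got kind '",
           curve_kind(c), "'")
  }
}

#' Total displacement between two proportional curves
#'
#' `D = sum_j |c1_j - c2_j|` over palaeolatitudinal bins: 0 for identical
#' curves, 2 for curves with disjoint support (maximum possible
#' difference). Bins missing in either curve are excluded and both
#' curves re-normalised over the jointly non-missing bins, preserving
#' the \[0, 2\] range.
#'
#' @param c1,c2 Proportional `lbg_curve`s on the same scheme.
#' @return The displacement `D`, or `NA` if no jointly non-missing bin
#'   has positive mass.
#' @export
total_displacement <- function(c1, c2) {
  .check_proportional(c1, c2)
  j <- .joint_bins(c1, c2)
  if (!length(j)) return(NA_real_)
  v1 <- as.numeric(c1)[j]; v2 <- as.numeric(c2)[j]
  if (sum(v1) == 0 || sum(v2) == 0) return(NA_real_)
  v1 <- v1 / sum(v1); v2 <- v2 / sum(v2)
  sum(abs(v1 - v2))
}

#' Per-bin model residuals between curves
#'
#' `test - reference` per jointly non-missing bin; positive residuals
#' mark bins where richness is over-represented in the test curve
#' (e.g. a sampled curve) relative to the reference (e.g. the simulated
#' truth).
#'
#' @param test,reference Proportional `lbg_curve`s on the same scheme.
#' @return A named numeric vector (one per bin; `NA` where either input
#'   is missing).
#' @export
curve_residuals <- function(test, reference) {
  .check_proportional(test, reference)
  out <- as.numeric(test) - as.numeric(reference)
  names(out) <- names(test)
  out
}

#' Pearson correlation between two curves
#'
#' Product-moment correlation over jointly non-missing bins with a
#' two-sided p-value from the t transform. Degenerate inputs (fewer than
#' 3 joint bins, or zero variance) yield `NA` results with
#' `defined = FALSE` rather than an error.
#'
#' @param c1,c2 `lbg_curve`s on the same scheme (any kind).
#' @return A list with `r`, `p`, `n` (bins used) and `defined`.
#' @export
pearson_r <- function(c1, c2) {
  stopifnot(inherits(c1, "lbg_curve"), inherits(c2, "lbg_curve"))
  j <- .joint_bins(c1, c2)
  x <- as.numeric(c1)[j]; y <- as.numeric(c2)[j]
  if (length(j) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(j),
                defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(j),
       defined = TRUE)
}

#' Kolmogorov-Smirnov two-sample test
#'
#' Supremum distance between the empirical distribution functions of two
#' value samples (by default the per-bin values of two richness curves),
#' with the asymptotic two-sided p-value.
#'
#' @param x,y Numeric samples (e.g. `as.numeric()` of two curves, or two
#'   `lbg_curve`s, whose missing bins are dropped).
#' @return A list with `ks_stat`, `p`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (inherits(x, "lbg_curve")) x <- as.numeric(x)
  if (inherits(y, "lbg_curve")) y <- as.numeric(y)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("ks_two_sample requires two non-empty samples")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(ks_stat = unname(kt$statistic), p = kt$p.value,
       n_x = length(x), n_y = length(y))
}

#' Peak bin and zone of a richness curve
#'
#' Locates the palaeolatitudinal bin with maximum richness. Exact ties
#' are broken toward the bin whose midpoint has the smallest absolute
#' latitude, with North preferred over South at equal absolute latitude,
#' and flagged. The zone (tropics, temperate, polar) follows the bin
#' midpoint.
#'
#' @param curve An `lbg_curve` with at least one non-missing bin.
#' @return A list with `bin_label`, `bin_index`, `zone`, `tie` and
#'   `value`.
#' @export
peak_location <- function(curve) {
  stopifnot(inherits(curve, "lbg_curve"))
  v <- as.numeric(curve)
  if (all(is.na(v))) stop("peak_location: curve is entirely missing")
  scheme <- curve_scheme(curve)
  mx <- max(v, na.rm = TRUE)
  cand <- which(!is.na(v) & v == mx)
  ord <- order(abs(scheme$mid[cand]), -sign(scheme$mid[cand]))
  pick <- cand[ord[1]]
  list(bin_label = scheme$label[pick], bin_index = pick,
       zone = scheme$zone[pick], tie = length(cand) > 1L, value = mx)
}

#' Coefficient of determination between paired series
#'
#' Squared Pearson correlation between a predictor (e.g. per-bin SSC or
#' summed MST length pooled over stages) and a richness series. Pairs
#' with undefined members are dropped and counted.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `r_squared`, `p`, `n_used`, `n_dropped`,
#'   `defined`.
#' @export
r_squared <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r_squared = NA_real_, p = NA_real_, n_used = length(x),
                n_dropped = n_dropped, defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r_squared = unname(ct$estimate)^2, p = ct$p.value,
       n_used = length(x), n_dropped = n_dropped, defined = TRUE)
}

#' Wilcoxon rank-sum contrast of two score series
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test between two series of
#' per-stage scores (e.g. displacement values under two treatments).
#' Small tie-free samples use the exact distribution; otherwise the
#' tie-corrected normal approximation applies (the default behaviour of
#' [stats::wilcox.test()]).
#'
#' @param a,b Numeric score series.
#' @return A list with `statistic` (the Mann-Whitney U of `a`), `p`,
#'   `n_a`, `n_b`.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Full pairwise comparison of two proportional curves
#'
#' Bundles displacement, correlation, KS test and peak reports for one
#' curve pair into a one-row data frame, the unit of the pipeline's
#' comparison tables.
#'
#' @param test,reference Proportional `lbg_curve`s.
#' @param pair_label Label describing the pair.
#' @return A one-row data frame with `stage_name`, `pair_label`, `D`,
#'   `r`, `r_p`, `ks_stat`, `ks_p`, `n_bins_used`, `peak_bin_test`,
#'   `peak_bin_ref`, `peak_zone_match`.
#' @export
compare_curves <- function(test, reference, pair_label = "test_vs_reference") {
  .check_proportional(test, reference)
  j <- .joint_bins(test, reference)
  pr <- pearson_r(test, reference)
  ks <- if (length(j)) ks_two_sample(as.numeric(test)[j],
                                     as.numeric(reference)[j])
        else list(ks_stat = NA_real_, p = NA_real_)
  pk_t <- if (!all(is.na(as.numeric(test)))) peak_location(test) else NULL
  pk_r <- if (!all(is.na(as.numeric(reference)))) peak_location(reference)
          else NULL
  data.frame(
    stage_name = attr(test, "stage_name"), pair_label = pair_label,
    D = total_displacement(test, reference),
    r = pr$r, r_p = pr$p, ks_stat = ks$ks_stat, ks_p = ks$p,
    n_bins_used = length(j),
    peak_bin_test = if (is.null(pk_t)) NA_character_ else pk_t$bin_label,
    peak_bin_ref = if (is.null(pk_r)) NA_character_ else pk_r$bin_label,
    peak_zone_match = if (is.null(pk_t) || is.null(pk_r)) NA
                      else pk_t$zone == pk_r$zone,
    stringsAsFactors = FALSE)
}
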