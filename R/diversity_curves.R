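# Latitudinal richness curves: raw distinct-species counts per
# palaeolatitudinal bin, classical rarefaction (bootstrap, with an
# analytic hypergeometric oracle), proportional normalisation, and
# missing-aware replicate averaging.

new_lbg_curve <- function(values, kind, stage_name,
                          scheme = lat_bin_scheme()) {
  stopifnot(length(values) == nrow(scheme),
            kind %in% c("raw", "rarefied", "proportional"))
  names(values) <- scheme$label
  structure(values, kind = kind, stage_name = stage_name, scheme = scheme,
            class = "lbg_curve")
}

#' @export
print.lbg_curve <- function(x, ...) {
  cat("<lbg_curve> kind:", attr(x, "kind"), " stage:",
      attr(x, "stage_name"), "\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

curve_kind <- function(curve) attr(curve, "kind")
curve_scheme <- function(curve) attr(curve, "scheme")

#' Raw latitudinal richness curve
#'
#' Counts the distinct species with at least one occurrence in each
#' palaeolatitudinal bin. A species ranging across several bins counts in
#' each of them.
#'
#' @param occurrences Occurrence table for a single stage.
#' @param scheme A [lat_bin_scheme()].
#' @param replicate Optional replicate number to subset to.
#' @return An `lbg_curve` of kind `"raw"` (integer counts; empty bins are
#'   0).
#' @export
bin_richness_curve <- function(occurrences, scheme = lat_bin_scheme(),
                               replicate = NULL) {
  if (!is.null(replicate))
    occurrences <- occurrences[occurrences$replicate %in% replicate, ,
                               drop = FALSE]
  stage_name <- if (nrow(occurrences)) occurrences$stage_name[1]
                else NA_character_
  vals <- numeric(nrow(scheme))
  if (nrow(occurrences)) {
    bin <- lat_bin_index(occurrences$lat, scheme)
    u <- unique(data.frame(bin = bin, sp = occurrences$species_id))
    cnt <- table(factor(u$bin, levels = seq_len(nrow(scheme))))
    vals <- as.numeric(cnt)
  }
  new_lbg_curve(vals, "raw", stage_name, scheme)
}

#' Global species richness of an occurrence table
#'
#' @param occurrences Occurrence table for a single stage.
#' @param replicate Optional replicate number to subset to.
#' @return The distinct `species_id` count.
#' @export
global_richness <- function(occurrences, replicate = NULL) {
  if (!is.null(replicate))
    occurrences <- occurrences[occurrences$replicate %in% replicate, ,
                               drop = FALSE]
  length(unique(occurrences$species_id))
}

#' Classical rarefaction of one bin's occurrence pool
#'
#' Bootstrap estimate of the expected species richness in a standard
#' quota of occurrences drawn without replacement from the bin: the mean
#' over `n_boot` draws of the distinct-species count per draw. Bins with
#' fewer occurrences than the quota have insufficient data and return
#' `NA`.
#'
#' @param species_ids Vector of species identities of the bin's
#'   occurrences (one element per occurrence record).
#' @param quota Occurrences drawn per bootstrap replicate.
#' @param n_boot Number of bootstrap replicates.
#' @return Mean rarefied richness, or `NA` if below quota. Uses the
#'   current RNG state.
#' @export
rarefied_richness <- function(species_ids, quota = 50L, n_boot = 1000L) {
  stopifnot(quota >= 1, n_boot >= 1)
  n <- length(species_ids)
  if (n < quota) return(NA_real_)
  draws <- vapply(seq_len(n_boot), function(i)
    length(unique(species_ids[sample.int(n, quota)])), numeric(1))
  mean(draws)
}

#' Exact expected rarefied richness (hypergeometric)
#'
#' Closed-form expectation of the distinct-species count in a draw of
#' `quota` occurrences without replacement:
#' `sum_i (1 - choose(N - N_i, quota) / choose(N, quota))` over species
#' abundances `N_i` with `N = sum(N_i)`. Serves as the analytic oracle
#' for [rarefied_richness()].
#'
#' @param counts Per-species occurrence counts (abundances).
#' @param quota Occurrences drawn; must not exceed `sum(counts)`.
#' @return The exact expectation.
#' @export
expected_rarefied_richness <- function(counts, quota) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (quota > n)
    stop("quota (", quota, ") exceeds total occurrence count (", n, ")")
  sum(1 - exp(lchoose(n - counts, quota) - lchoose(n, quota)))
}

#' Rarefied latitudinal richness curve
#'
#' Applies [rarefied_richness()] to each bin's occurrence pool. Bins
#' below quota are missing (`NA`), not zero.
#'
#' @param occurrences Occurrence table for a single stage (one
#'   replicate).
#' @param scheme A [lat_bin_scheme()].
#' @param quota,n_boot Passed to [rarefied_richness()].
#' @param replicate Optional replicate number to subset to.
#' @return An `lbg_curve` of kind `"rarefied"`.
#' @export
rarefied_curve <- function(occurrences, scheme = lat_bin_scheme(),
                           quota = 50L, n_boot = 1000L,
                           replicate = NULL) {
  if (!is.null(replicate))
    occurrences <- occurrences[occurrences$replicate %in% replicate, ,
                               drop = FALSE]
  stage_name <- if (nrow(occurrences)) occurrences$stage_name[1]
                else NA_character_
  vals <- rep(NA_real_, nrow(scheme))
  if (nrow(occurrences)) {
    bin <- lat_bin_index(occurrences$lat, scheme)
    for (b in unique(bin))
      vals[b] <- rarefied_richness(occurrences$species_id[bin == b],
                                   quota, n_boot)
  }
  new_lbg_curve(vals, "rarefied", stage_name, scheme)
}

#' Proportional richness curve
#'
#' Divides each bin's richness by the sum of richness across bins, so
#' values total 1 and curves of different treatments compare by shape
#' alone. Missing bins stay missing; an all-zero or all-missing curve
#' becomes all missing, with a warning.
#'
#' @param curve An `lbg_curve` of kind `"raw"` or `"rarefied"`.
#' @return An `lbg_curve` of kind `"proportional"`.
#' @export
normalize_proportional <- function(curve) {
  stopifnot(inherits(curve, "lbg_curve"))
  v <- as.numeric(curve)
  s <- sum(v, na.rm = TRUE)
  if (!any(!is.na(v)) || s == 0) {
    warning("curve has no positive richness; proportional curve is all missing")
    v[] <- NA_real_
  } else {
    v <- v / s
  }
  new_lbg_curve(v, "proportional", attr(curve, "stage_name"),
                curve_scheme(curve))
}

#' Missing-aware mean of replicate curves
#'
#' Per-bin mean over replicates, using only replicates where the bin is
#' non-missing; a bin is missing in the mean only if missing in every
#' replicate.
#'
#' @param curves A list of `lbg_curve`s of the same kind, stage and
#'   scheme.
#' @return An `lbg_curve` of the same kind.
#' @export
mean_curve <- function(curves) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "lbg_curve")))
  kinds <- vapply(curves, curve_kind, character(1))
  if (length(unique(kinds)) != 1L)
    stop("cannot average curves of mixed kinds: ",
         paste(unique(kinds), collapse = ", "))
  m <- do.call(rbind, lapply(curves, as.numeric))
  v <- colMeans(m, na.rm = TRUE)
  v[colSums(!is.na(m)) == 0L] <- NA_real_
  new_lbg_curve(v, kinds[1], attr(curves[[1]], "stage_name"),
                curve_scheme(curves[[1]]))
}

#' Curves as a long data frame
#'
#' @param curve An `lbg_curve`.
#' @return Data frame `stage_name`, `bin_label`, `kind`, `value`,
#'   `missing`.
#' @export
curve_as_df <- function(curve) {
  stopifnot(inherits(curve, "lbg_curve"))
  data.frame(stage_name = attr(curve, "stage_name"),
             bin_label = names(curve), kind = curve_kind(curve),
             value = as.numeric(curve), missing = is.na(as.numeric(curve)),
             stringsAsFactors = FALSE)
}
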