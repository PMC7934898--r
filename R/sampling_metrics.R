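# Spatial sampling metrics: spatial sampling coverage (SSC) and summed
# minimum-spanning-tree (MST) length, globally and per 15-degree
# palaeolatitudinal bin.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (volumetric mean
#' Earth radius). Vectorised with recycling; longitudes may use any
#' convention, the formula handles wraparound.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @return Distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1)  # one degree of arc: 111.19 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * r * asin(sqrt(a))
}

#' Palaeolatitudinal bin scheme
#'
#' Partitions \[-90, 90) into equal-width latitude bins (default 15
#' degrees, giving 12 bins) and assigns each to a climate zone by the
#' absolute latitude of its midpoint: tropics (< 30), temperate
#' (30 to < 60), polar (>= 60).
#'
#' @param width Bin width in degrees; must divide 180.
#' @return A data frame with `lower`, `upper`, `mid`, `label` (e.g.
#'   `"30_45N"`, `"75_90S"`) and `zone`.
#' @export
lat_bin_scheme <- function(width = 15) {
  stopifnot(width > 0, 180 %% width == 0)
  lower <- seq(-90, 90 - width, by = width)
  upper <- lower + width
  mid <- (lower + upper) / 2
  label <- ifelse(upper <= 0,
                  paste0(abs(upper), "_", abs(lower), "S"),
                  paste0(lower, "_", upper, "N"))
  zone <- ifelse(abs(mid) < 30, "tropics",
                 ifelse(abs(mid) < 60, "temperate", "polar"))
  data.frame(lower = lower, upper = upper, mid = mid, label = label,
             zone = zone, stringsAsFactors = FALSE)
}

#' Bin index of latitudes under a bin scheme
#'
#' @param lat Latitudes in degrees; 90 collapses into the northernmost
#'   bin.
#' @param scheme A [lat_bin_scheme()].
#' @return Integer bin indices (1-based into `scheme`).
#' @export
lat_bin_index <- function(lat, scheme = lat_bin_scheme()) {
  width <- scheme$upper[1] - scheme$lower[1]
  i <- pmin(floor((lat + 90) / width), nrow(scheme) - 1L) + 1L
  as.integer(i)
}

#' Spatial sampling coverage
#'
#' SSC is the percentage of sampled cells within a chosen set of
#' available cells (the shallow-marine grid), computed globally or within
#' palaeolatitudinal bins. Bins with no available cells report `NA`
#' coverage (undefined), which is distinct from 0.
#'
#' @param window A `sampling_window` (see [rasterize_window()]).
#' @param mask The stage's `shallow_mask`; the window must be a subset.
#' @param scope `"global"` or `"bin"`.
#' @param scheme Bin scheme used when `scope = "bin"`.
#' @return A data frame with one row per scope unit: `stage_name`,
#'   `scope` (`"global"` or a bin label), `ssc_percent`, `n_sampled`,
#'   `n_available`.
#' @export
spatial_sampling_coverage <- function(window, mask,
                                      scope = c("global", "bin"),
                                      scheme = lat_bin_scheme()) {
  scope <- match.arg(scope)
  stopifnot(inherits(window, "sampling_window"),
            inherits(mask, "shallow_mask"))
  mask_key <- paste(mask$row, mask$col)
  win_key <- paste(window$row, window$col)
  if (!all(win_key %in% mask_key))
    stop("sampling window contains cells outside the shallow-marine mask")
  stage_name <- attr(window, "stage_name")
  if (scope == "global") {
    n_s <- length(win_key); n_a <- length(mask_key)
    return(data.frame(stage_name = stage_name, scope = "global",
                      ssc_percent = 100 * n_s / n_a,
                      n_sampled = n_s, n_available = n_a,
                      stringsAsFactors = FALSE))
  }
  bin_m <- lat_bin_index(mask$lat, scheme)
  bin_w <- lat_bin_index(window$lat, scheme)
  n_a <- tabulate(bin_m, nbins = nrow(scheme))
  n_s <- tabulate(bin_w, nbins = nrow(scheme))
  data.frame(stage_name = stage_name, scope = scheme$label,
             ssc_percent = ifelse(n_a > 0, 100 * n_s / n_a, NA_real_),
             n_sampled = n_s, n_available = n_a,
             stringsAsFactors = FALSE)
}

#' Summed minimum-spanning-tree length of a sampling window
#'
#' Length (km) of the minimum spanning tree over the sampled cell
#' centroids under great-circle distances: the minimum total length of
#' segments connecting all sampled cells. Windows (or bins) with one or
#' zero sampled cells score 0. Per-bin trees connect only cells within
#' the bin.
#'
#' @param window A `sampling_window`.
#' @param scope `"global"` or `"bin"`.
#' @param scheme Bin scheme used when `scope = "bin"`.
#' @return A data frame with `stage_name`, `scope`, `mst_km`,
#'   `n_sampled`.
#' @export
summed_mst_length <- function(window, scope = c("global", "bin"),
                              scheme = lat_bin_scheme()) {
  scope <- match.arg(scope)
  stopifnot(inherits(window, "sampling_window"))
  stage_name <- attr(window, "stage_name")
  if (scope == "global") {
    return(data.frame(stage_name = stage_name, scope = "global",
                      mst_km = .mst_km(window$lat, window$lon),
                      n_sampled = nrow(window), stringsAsFactors = FALSE))
  }
  bin <- lat_bin_index(window$lat, scheme)
  mst <- vapply(seq_len(nrow(scheme)), function(b) {
    sel <- bin == b
    .mst_km(window$lat[sel], window$lon[sel])
  }, numeric(1))
  data.frame(stage_name = stage_name, scope = scheme$label, mst_km = mst,
             n_sampled = tabulate(bin, nbins = nrow(scheme)),
             stringsAsFactors = FALSE)
}

# MST length over points, via vegan::spantree on the great-circle
# distance matrix; nodes are ordered lexicographically by (lat, lon) so
# ties among equal-weight edges resolve deterministically.
.mst_km <- function(lat, lon) {
  n <- length(lat)
  if (n <= 1L) return(0)
  o <- order(lat, lon)
  lat <- lat[o]; lon <- lon[o]
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d[j, i] <- d[i, j] <- great_circle_km(lat[i], lon[i], lat[j], lon[j])
  }
  tr <- vegan::spantree(stats::as.dist(d))
  sum(tr$dist)
}
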