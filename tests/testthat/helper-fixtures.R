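# Shared fixtures and independent oracles for the test suite.

# latitudinally uniform shelf: a band of longitudes across all latitudes
make_band_mask <- function(n_lon = 10L, stage_name = "uniform") {
  rows <- rep(seq_len(180L), each = n_lon)
  cols <- rep(seq_len(n_lon) + 170L, times = 180L)
  shallow_mask_from_cells(rows, cols, stage_name)
}

# hand-built elevation grid from a value matrix (180 x 360, south-first)
make_elev_grid <- function(values, stage_name = "synthetic") {
  structure(list(values = values, stage_name = stage_name,
                 spec = grid_spec()),
            class = "elevation_grid")
}

# proportional curve from explicit bin values (normalised here)
make_prop_curve <- function(values, stage_name = "test") {
  raw <- lbgwin:::new_lbg_curve(values, "raw", stage_name)
  normalize_proportional(raw)
}

# independent haversine oracle on the same 6371 km sphere (geosphere's
# implementation, not the package's)
oracle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371)
}

# --- exhaustive minimum-spanning-tree oracle (Pruefer enumeration) ----

prufer_to_edges <- function(pr, n) {
  degree <- rep(1L, n)
  for (v in pr) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (i in seq_along(pr)) {
    leaf <- which.max(degree == 1L)       # smallest remaining leaf
    edges[i, ] <- c(leaf, pr[i])
    degree[leaf] <- 0L
    degree[pr[i]] <- degree[pr[i]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

# minimum spanning tree length by enumerating all n^(n-2) labelled trees
mst_bruteforce_km <- function(lat, lon) {
  n <- length(lat)
  if (n <= 1L) return(0)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- great_circle_km(lat[i], lon[i], lat[j], lon[j])
  if (n == 2L) return(d[1, 2])
  prufers <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (k in seq_len(nrow(prufers))) {
    e <- prufer_to_edges(as.integer(prufers[k, ]), n)
    best <- min(best, sum(d[e]))
  }
  best
}

# small occurrence-table fixture builder
make_occ <- function(species_id, lat, lon, replicate = 1L,
                     stage_name = "test") {
  cells <- latlon_to_cell(lat, lon)
  ctr <- cell_center(cells$row, cells$col)
  data.frame(replicate = replicate, stage_name = stage_name,
             species_id = species_id, cell_row = cells$row,
             cell_col = cells$col, lat = ctr$lat, lon = ctr$lon,
             stringsAsFactors = FALSE)
}
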