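# 1 degree x 1 degree global grid: 180 rows (latitude, south to north) by
# 360 columns (longitude, west to east). Cell (row, col), 1-based, is
# centred at (row - 90.5, col - 180.5); a point maps to its cell by
# flooring (lat + 90) and (lon + 180). Longitudes live on [-180, 180).

#' Global 1-degree grid specification
#'
#' @return A list with `res` (1), `n_lat` (180) and `n_lon` (360), of class
#'   `grid_spec`.
#' @export
grid_spec <- function() {
  structure(list(res = 1, n_lat = 180L, n_lon = 360L), class = "grid_spec")
}

#' Map points to grid cells
#'
#' @param lat,lon Numeric vectors of coordinates in degrees; `lat` in
#'   \[-90, 90\] (90 collapses into the northernmost row), `lon` any value,
#'   wrapped onto \[-180, 180).
#' @return A data frame with integer columns `row` and `col` (1-based; row
#'   1 is the southernmost band, col 1 the westernmost).
#' @export
latlon_to_cell <- function(lat, lon) {
  stopifnot(all(is.finite(lat)), all(is.finite(lon)),
            all(lat >= -90), all(lat <= 90))
  row <- pmin(floor(lat + 90), 179) + 1L
  col <- floor((lon + 180) %% 360) + 1L
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Grid-cell centres
#'
#' @param row,col Integer vectors of 1-based cell indices.
#' @return A data frame with `lat` and `lon` cell-centre coordinates at
#'   half degrees.
#' @export
cell_center <- function(row, col) {
  data.frame(lat = row - 90.5, lon = col - 180.5)
}

#' Parameters for the synthetic palaeogeography generator
#'
#' The generator places a small number of elliptical continental plates on
#' the sphere, each with a positive-elevation land core, a shelf apron
#' whose depth grades linearly from the shoreline to 200 m, and deep ocean
#' elsewhere. Plate centres drift by a fixed angular step per stage index,
#' so successive stages share most of their land.
#'
#' @param n_continents Number of continental plates.
#' @param land_radius Two-element range (degrees of arc) from which each
#'   plate's land radius is drawn.
#' @param shelf_width Width of the shallow shelf apron, degrees of arc.
#' @param drift_per_stage Angular drift of each plate centre per stage
#'   index, degrees.
#' @param ocean_depth Deep-ocean elevation, metres (negative).
#' @param land_height Peak land elevation, metres.
#' @return A list of class `geo_params`.
#' @export
synthetic_geo_params <- function(n_continents = 4L,
                                 land_radius = c(18, 28),
                                 shelf_width = 8,
                                 drift_per_stage = 0.7,
                                 ocean_depth = -4000,
                                 land_height = 500) {
  stopifnot(n_continents >= 1, length(land_radius) == 2L,
            all(land_radius > 0), shelf_width > 0, ocean_depth < -200,
            land_height > 0)
  structure(list(n_continents = as.integer(n_continents),
                 land_radius = land_radius, shelf_width = shelf_width,
                 drift_per_stage = drift_per_stage,
                 ocean_depth = ocean_depth, land_height = land_height),
            class = "geo_params")
}

#' Synthetic stage-level digital elevation model
#'
#' Builds a deterministic global 1-degree elevation grid for one
#' stratigraphic stage: elliptical continental plates (land, elevation
#' > 0) fringed by shallow shelves (elevation in \[-200, 0)) over deep
#' ocean. Plate positions are seeded once and drift with the stage index,
#' so grids for adjacent stages under the same seed differ only slightly.
#'
#' @param stage A stage identifier accepted by [stage_bin()].
#' @param geo_params A [synthetic_geo_params()] list.
#' @param seed Integer seed; fixes plate geometry across all stages.
#' @return An object of class `elevation_grid`: list with `values` (180 x
#'   360 matrix, metres; rows south to north), `stage_name` and `spec`.
#' @export
generate_synthetic_dem <- function(stage, geo_params = synthetic_geo_params(),
                                   seed = 1L) {
  stage <- stage_bin(stage)
  stopifnot(inherits(geo_params, "geo_params"))
  p <- geo_params
  # plate geometry drawn from the seed only, so it is shared by all stages
  plates <- local({
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    list(lat0 = stats::runif(p$n_continents, -55, 55),
         lon0 = stats::runif(p$n_continents, -180, 180),
         radius = stats::runif(p$n_continents, p$land_radius[1],
                               p$land_radius[2]),
         bearing = stats::runif(p$n_continents, 0, 2 * pi))
  })
  s <- stage$index
  ctr_lat <- pmax(-80, pmin(80,
    plates$lat0 + s * p$drift_per_stage * sin(plates$bearing)))
  ctr_lon <- ((plates$lon0 + s * p$drift_per_stage * cos(plates$bearing) +
                 180) %% 360) - 180

  spec <- grid_spec()
  cells <- cell_center(rep(seq_len(spec$n_lat), spec$n_lon),
                       rep(seq_len(spec$n_lon), each = spec$n_lat))
  elev <- rep(p$ocean_depth, nrow(cells))
  for (i in seq_len(p$n_continents)) {
    d <- .central_angle_deg(cells$lat, cells$lon, ctr_lat[i], ctr_lon[i])
    r <- plates$radius[i]
    e <- ifelse(d < r,
                p$land_height * (1 - d / r) + 1,
                ifelse(d < r + p$shelf_width,
                       -1 - 199 * (d - r) / p$shelf_width,
                       p$ocean_depth))
    elev <- pmax(elev, e)
  }
  values <- matrix(elev, nrow = spec$n_lat, ncol = spec$n_lon)
  if (!any(values >= -200 & values < 0))
    stop("geo_params yield no shallow-marine cells at stage ", stage$name)
  if (!any(values < 0))
    stop("geo_params yield no marine cells at stage ", stage$name)
  structure(list(values = values, stage_name = stage$name, spec = spec),
            class = "elevation_grid")
}

# great-circle central angle in degrees (spherical law of haversines)
.central_angle_deg <- function(lat1, lon1, lat2, lon2) {
  great_circle_km(lat1, lon1, lat2, lon2) / (pi * 6371 / 180)
}

#' Shallow-marine mask of an elevation grid
#'
#' Retains exactly the cells with elevation in \[-200, 0): depths down to
#' and including 200 m, approximating the photic zone. Cells at exactly
#' 0 m count as shoreline/land.
#'
#' @param dem An `elevation_grid`.
#' @return An object of class `shallow_mask`: data frame of `row`, `col`,
#'   `lat`, `lon` (cell centres) with attributes `stage_name` and `spec`.
#' @export
shallow_marine_mask <- function(dem) {
  stopifnot(inherits(dem, "elevation_grid"))
  idx <- which(dem$values >= -200 & dem$values < 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("elevation grid has no shallow-marine cells (-200 <= elev < 0)")
  ctr <- cell_center(idx[, 1], idx[, 2])
  out <- data.frame(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
                    lat = ctr$lat, lon = ctr$lon)
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, stage_name = dem$stage_name, spec = dem$spec,
            class = c("shallow_mask", "data.frame"))
}

#' Construct a shallow-marine mask from explicit cells
#'
#' Mainly useful for building bespoke geographies (e.g. latitudinally
#' uniform shelves) in experiments and tests.
#'
#' @param row,col Integer vectors of 1-based cell indices.
#' @param stage_name Stage label attached to the mask.
#' @return A `shallow_mask`.
#' @export
shallow_mask_from_cells <- function(row, col, stage_name = "synthetic") {
  stopifnot(length(row) == length(col), length(row) >= 1,
            all(row >= 1), all(row <= 180), all(col >= 1), all(col <= 360))
  ctr <- cell_center(row, col)
  out <- data.frame(row = as.integer(row), col = as.integer(col),
                    lat = ctr$lat, lon = ctr$lon)
  out <- unique(out[order(out$row, out$col), , drop = FALSE])
  rownames(out) <- NULL
  structure(out, stage_name = stage_name, spec = grid_spec(),
            class = c("shallow_mask", "data.frame"))
}

#' Write an elevation grid as a headered ASCII raster
#'
#' Esri ASCII grid dialect: six header lines (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' `nrows` rows of values, northernmost row first. Values are written at
#' full double precision so a write/read round trip is exact.
#'
#' @param dem An `elevation_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(dem, path) {
  stopifnot(inherits(dem, "elevation_grid"))
  spec <- dem$spec
  hdr <- c(paste("ncols", spec$n_lon),
           paste("nrows", spec$n_lat),
           "xllcorner -180",
           "yllcorner -90",
           paste("cellsize", spec$res),
           "NODATA_value -9999")
  rows <- apply(dem$values[rev(seq_len(spec$n_lat)), , drop = FALSE], 1,
                function(v) paste(formatC(v, format = "g", digits = 17),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a headered ASCII raster as an elevation grid
#'
#' @param path File in the Esri ASCII grid dialect written by
#'   [write_ascii_grid()]. Only global 1-degree grids (360 x 180, corner
#'   at -180, -90) are accepted.
#' @param stage_name Stage label to attach; the dialect itself carries
#'   none.
#' @return An `elevation_grid`.
#' @export
read_ascii_grid <- function(path, stage_name = NA_character_) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("malformed ASCII grid: fewer than 7 lines")
  hdr_names <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                 "NODATA_value")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed ASCII grid header line ", i, ": ", lines[i])
    key <- parts[1]
    if (!tolower(key) %in% tolower(hdr_names))
      stop("malformed ASCII grid: unexpected header field '", key, "'")
    hdr[[tolower(key)]] <- as.numeric(parts[2])
  }
  missing <- setdiff(tolower(hdr_names), names(hdr))
  if (length(missing))
    stop("malformed ASCII grid: missing header field '", missing[1], "'")
  if (hdr$cellsize != 1)
    stop("unsupported resolution: cellsize must be 1 degree, got ",
         hdr$cellsize)
  if (hdr$ncols != 360 || hdr$nrows != 180)
    stop("unsupported extent: expected 360 x 180 global grid, got ",
         hdr$ncols, " x ", hdr$nrows)
  if (hdr$xllcorner != -180 || hdr$yllcorner != -90)
    stop("unsupported origin: expected corner (-180, -90), got (",
         hdr$xllcorner, ", ", hdr$yllcorner, ")")
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != 180L)
    stop("malformed ASCII grid: expected 180 data rows, found ",
         length(body))
  vals <- lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  n <- lengths(vals)
  if (any(n != 360L))
    stop("malformed ASCII grid: data row with ", n[n != 360][1],
         " values (expected 360)")
  m <- do.call(rbind, vals)
  m[m == hdr$nodata_value] <- NA_real_
  if (anyNA(m)) stop("ASCII grid contains NODATA cells; grid must be full")
  values <- m[rev(seq_len(180L)), , drop = FALSE]  # back to south-first
  dimnames(values) <- NULL
  structure(list(values = values, stage_name = stage_name,
                 spec = grid_spec()),
            class = "elevation_grid")
}

# RNG bookkeeping: functions that seed internally restore the caller's
# RNG state so package calls never perturb a user's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
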