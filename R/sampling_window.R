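# Per-stage spatial sampling windows: the set of 1-degree cells deemed
# sampled (containing at least one fossil collection), clipped to the
# stage's shallow-marine mask. Windows come from a PBDB-style collection
# table or from a synthetic generator emulating the heterogeneity of the
# real fossil record.

#' Read a PBDB-style collection table
#'
#' Expects a CSV using Paleobiology Database API column names:
#' `collection_no`, `paleolat`, `paleolng`, `max_ma`, `min_ma` (extra
#' columns are ignored). Rows with missing palaeocoordinates are dropped
#' with a message giving the count.
#'
#' @param path CSV file path.
#' @return A data frame with `collection_no`, `paleolat`, `paleolng`,
#'   `max_ma`, `min_ma`.
#' @export
read_collections <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("collection_no", "paleolat", "paleolng", "max_ma", "min_ma")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("collection table is missing required column(s): ",
         paste(missing, collapse = ", "))
  tab <- tab[, req, drop = FALSE]
  for (v in c("paleolat", "paleolng", "max_ma", "min_ma"))
    tab[[v]] <- suppressWarnings(as.numeric(tab[[v]]))
  bad <- is.na(tab$paleolat) | is.na(tab$paleolng)
  if (any(bad)) {
    message("read_collections: dropped ", sum(bad),
            " row(s) with missing palaeocoordinates")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (any(tab$max_ma < tab$min_ma, na.rm = TRUE))
    stop("collection table has rows with max_ma < min_ma")
  if (any(abs(tab$paleolat) > 90) || any(abs(tab$paleolng) > 180))
    stop("collection table has palaeocoordinates out of range")
  rownames(tab) <- NULL
  tab
}

#' Assign collections to a stratigraphic stage
#'
#' The default rule assigns a collection to the stage whose interval
#' `(age_top, age_base]` contains its age midpoint
#' `(max_ma + min_ma) / 2`; every collection lands in exactly one stage.
#' The stricter `"contain"` rule keeps only collections whose full age
#' range lies within the stage.
#'
#' @param collections A collection table ([read_collections()]).
#' @param stage A stage identifier accepted by [stage_bin()].
#' @param rule `"midpoint"` (default) or `"contain"`.
#' @return The subset of `collections` assigned to the stage.
#' @export
assign_to_stage <- function(collections, stage,
                            rule = c("midpoint", "contain")) {
  rule <- match.arg(rule)
  stage <- stage_bin(stage)
  if (nrow(collections) == 0L) return(collections)
  keep <- if (rule == "midpoint") {
    mid <- (collections$max_ma + collections$min_ma) / 2
    mid > stage$age_top & mid <= stage$age_base
  } else {
    collections$max_ma <= stage$age_base &
      collections$min_ma >= stage$age_top
  }
  out <- collections[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.new_window <- function(row, col, stage_name) {
  if (length(row)) {
    ctr <- cell_center(row, col)
    out <- data.frame(row = as.integer(row), col = as.integer(col),
                      lat = ctr$lat, lon = ctr$lon)
    out <- unique(out[order(out$row, out$col), , drop = FALSE])
  } else {
    out <- data.frame(row = integer(), col = integer(), lat = numeric(),
                      lon = numeric())
  }
  rownames(out) <- NULL
  structure(out, stage_name = stage_name, spec = grid_spec(),
            class = c("sampling_window", "data.frame"))
}

#' Rasterise stage-assigned collections into a sampling window
#'
#' A grid cell is deemed sampled if at least one collection falls within
#' it; the sampled set is then clipped to the shallow-marine mask (cells
#' on land or in deep water are discarded, not snapped).
#'
#' @param collections Stage-assigned collection table.
#' @param mask The stage's `shallow_mask`.
#' @return A `sampling_window`: data frame `row`, `col`, `lat`, `lon`
#'   with attribute `stage_name`.
#' @export
rasterize_window <- function(collections, mask) {
  stopifnot(inherits(mask, "shallow_mask"))
  if (nrow(collections) == 0L)
    return(.new_window(integer(), integer(), attr(mask, "stage_name")))
  cells <- unique(latlon_to_cell(collections$paleolat,
                                 collections$paleolng))
  keep <- paste(cells$row, cells$col) %in% paste(mask$row, mask$col)
  .new_window(cells$row[keep], cells$col[keep], attr(mask, "stage_name"))
}

#' Generate a synthetic sampling window
#'
#' Emulates the heterogeneity of the real fossil sampling window: a fixed
#' number of shallow-marine cells -- `round(target_ssc/100 * nrow(mask))`
#' -- are drawn without replacement (so global SSC is exact by
#' construction), with selection weight following a Gaussian in latitude
#' centred on `mu` (default 37.5 degrees N, matching the skew of fossil
#' collections toward 30-45 N), and with each latitudinal bin
#' independently zeroed out with probability `p_zero_bin` (emulating the
#' roughly 40% of bins with no sampling at all).
#'
#' @param mask A `shallow_mask`.
#' @param target_ssc Target global spatial sampling coverage, percent.
#' @param mu,sigma Centre and width (degrees) of the latitudinal
#'   selection weight.
#' @param p_zero_bin Probability that a 15-degree bin is entirely
#'   unsampled.
#' @param scheme Bin scheme for the zeroing step.
#' @param seed Integer seed.
#' @return A `sampling_window`.
#' @export
generate_synthetic_window <- function(mask, target_ssc = 0.7, mu = 37.5,
                                      sigma = 15, p_zero_bin = 0.4,
                                      scheme = lat_bin_scheme(),
                                      seed = 1L) {
  stopifnot(inherits(mask, "shallow_mask"), target_ssc >= 0,
            target_ssc <= 100, sigma > 0, p_zero_bin >= 0, p_zero_bin < 1)
  n_target <- round(target_ssc / 100 * nrow(mask))
  if (n_target == 0L)
    return(.new_window(integer(), integer(), attr(mask, "stage_name")))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  zero_bin <- stats::runif(nrow(scheme)) < p_zero_bin
  w <- exp(-(mask$lat - mu)^2 / (2 * sigma^2))
  w[zero_bin[lat_bin_index(mask$lat, scheme)]] <- 0
  avail <- sum(w > 0)
  if (avail == 0L) {   # every populated bin zeroed out; fall back to skew only
    w <- exp(-(mask$lat - mu)^2 / (2 * sigma^2))
    avail <- nrow(mask)
  }
  if (n_target > avail)
    stop("target SSC requires ", n_target, " cells but only ", avail,
         " are selectable")
  idx <- sample.int(nrow(mask), n_target, replace = FALSE, prob = w)
  .new_window(mask$row[idx], mask$col[idx], attr(mask, "stage_name"))
}

#' Build a sampling window covering an entire mask
#'
#' The identity window: every shallow-marine cell is sampled. Filtering
#' through it leaves occurrence tables unchanged.
#'
#' @param mask A `shallow_mask`.
#' @return A `sampling_window` equal to the mask's cell set.
#' @export
full_window <- function(mask) {
  stopifnot(inherits(mask, "shallow_mask"))
  .new_window(mask$row, mask$col, attr(mask, "stage_name"))
}

#' Filter occurrences through a sampling window
#'
#' Retains exactly the occurrence records whose cell belongs to the
#' window, preserving record order.
#'
#' @param occurrences An occurrence table ([simulate_assemblage()]).
#' @param window A `sampling_window` for the same stage.
#' @return The filtered occurrence table.
#' @export
apply_window <- function(occurrences, window) {
  stopifnot(inherits(window, "sampling_window"))
  if (nrow(occurrences) == 0L) return(occurrences)
  ws <- attr(window, "stage_name")
  if (!is.null(ws) && !is.na(ws) &&
      !all(occurrences$stage_name == ws))
    stop("stage mismatch: window is for stage '", ws, "'")
  keep <- paste(occurrences$cell_row, occurrences$cell_col) %in%
    paste(window$row, window$col)
  out <- occurrences[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise a sampling window as CSV
#'
#' @param window A `sampling_window`.
#' @param path Output path. Columns: `stage_name`, `cell_row`,
#'   `cell_col`.
#' @return `path`, invisibly.
#' @export
write_window <- function(window, path) {
  stopifnot(inherits(window, "sampling_window"))
  utils::write.csv(
    data.frame(stage_name = attr(window, "stage_name"),
               cell_row = window$row, cell_col = window$col),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a sampling window from CSV
#'
#' @param path CSV written by [write_window()].
#' @return A `sampling_window`.
#' @export
read_window <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("stage_name", "cell_row", "cell_col")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("window file is missing required column(s): ",
         paste(missing, collapse = ", "))
  stage_name <- if (nrow(tab)) tab$stage_name[1] else NA_character_
  .new_window(tab$cell_row, tab$cell_col, stage_name)
}
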