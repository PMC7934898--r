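# 56-stage Permian-Neogene scaffold, Asselian (298.9 Ma) to Piacenzian
# (2.58 Ma), following the International Chronostratigraphic Chart.
# Boundaries are stored once per internal boundary so contiguity holds by
# construction.

.stage_names <- c(
  # Permian (9)
  "Asselian", "Sakmarian", "Artinskian", "Kungurian", "Roadian", "Wordian",
  "Capitanian", "Wuchiapingian", "Changhsingian",
  # Triassic (7)
  "Induan", "Olenekian", "Anisian", "Ladinian", "Carnian", "Norian",
  "Rhaetian",
  # Jurassic (11)
  "Hettangian", "Sinemurian", "Pliensbachian", "Toarcian", "Aalenian",
  "Bajocian", "Bathonian", "Callovian", "Oxfordian", "Kimmeridgian",
  "Tithonian",
  # Cretaceous (12)
  "Berriasian", "Valanginian", "Hauterivian", "Barremian", "Aptian",
  "Albian", "Cenomanian", "Turonian", "Coniacian", "Santonian", "Campanian",
  "Maastrichtian",
  # Palaeogene (9)
  "Danian", "Selandian", "Thanetian", "Ypresian", "Lutetian", "Bartonian",
  "Priabonian", "Rupelian", "Chattian",
  # Neogene (8)
  "Aquitanian", "Burdigalian", "Langhian", "Serravallian", "Tortonian",
  "Messinian", "Zanclean", "Piacenzian")

.stage_periods <- rep(
  c("Permian", "Triassic", "Jurassic", "Cretaceous", "Palaeogene",
    "Neogene"),
  times = c(9L, 7L, 11L, 12L, 9L, 8L))

#' Stratigraphic stage table (Asselian to Piacenzian)
#'
#' Returns the 56-stage scaffold spanning the beginning of the Permian to
#' the end of the Neogene (298.9-2.58 Ma), ordered oldest to youngest with
#' contiguous, non-overlapping age bounds.
#'
#' @return A data frame with columns `name`, `period`, `age_base` (older
#'   bound, Ma), `age_top` (younger bound, Ma) and `index` (0 = oldest,
#'   55 = youngest).
#' @examples
#' st <- build_stage_table()
#' nrow(st)          # 56
#' st$name[1]        # "Asselian"
#' sum(st$age_base - st$age_top)  # 296.32 Myr of contiguous time
#' @export
build_stage_table <- function() {
  bounds <- .stage_boundary_ages()
  data.frame(
    name = .stage_names,
    period = .stage_periods,
    age_base = bounds[-length(bounds)],
    age_top = bounds[-1L],
    index = seq_along(.stage_names) - 1L,
    stringsAsFactors = FALSE)
}

.stage_boundary_ages <- function() {
  c(298.9, 293.52, 290.1, 283.5, 273.01, 266.9, 264.28, 259.51, 254.14,
    251.902,                                        # base Triassic
    251.2, 247.2, 242, 237, 227, 208.5,
    201.3,                                          # base Jurassic
    199.3, 190.8, 182.7, 174.1, 170.3, 168.3, 166.1, 163.5, 157.3, 152.1,
    145,                                            # base Cretaceous
    139.8, 132.9, 129.4, 125, 113, 100.5, 93.9, 89.8, 86.3, 83.6, 72.1,
    66,                                             # base Palaeogene
    61.6, 59.2, 56, 47.8, 41.2, 37.71, 33.9, 27.82,
    23.03,                                          # base Neogene
    20.44, 15.97, 13.82, 11.63, 7.246, 5.333, 3.6, 2.58)
}

#' Look up one stage by name or index
#'
#' @param stage A stage name (e.g. `"Hettangian"`), a 0-based stage index,
#'   or a one-row subset of [build_stage_table()] (returned unchanged).
#' @return A one-row data frame from [build_stage_table()].
#' @export
stage_bin <- function(stage) {
  if (is.data.frame(stage)) {
    stopifnot(nrow(stage) == 1L,
              all(c("name", "age_base", "age_top", "index") %in%
                    names(stage)))
    return(stage)
  }
  st <- build_stage_table()
  if (is.character(stage)) {
    i <- match(stage, st$name)
    if (is.na(i)) stop("unknown stage name: ", stage)
  } else {
    i <- as.integer(stage) + 1L
    if (is.na(i) || i < 1L || i > nrow(st))
      stop("stage index out of range [0, 55]: ", stage)
  }
  st[i, , drop = FALSE]
}

#' Write the stage table as CSV
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(path) {
  utils::write.csv(build_stage_table(), path, row.names = FALSE)
  invisible(path)
}
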