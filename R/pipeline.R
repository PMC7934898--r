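# Experiment orchestration: geography -> simulation -> windowing ->
# sampling metrics -> richness curves -> comparisons, from one config,
# with a documented seed-derivation scheme, optional CSV output and a
# run manifest.

#' Build an experiment configuration
#'
#' Defaults mirror the full study design (all 56 stages, three LBG
#' types, 1000 species, 100 replicates, rarefaction quota 50 with 1000
#' bootstraps); tests and quickstarts should scale `stages`,
#' `n_species`, `n_replicates` and `n_boot` down.
#'
#' @param stages Stage selection: vector of stage names or 0-based
#'   indices; `NULL` means all 56.
#' @param lbg_types Subset of `c("flat", "unimodal", "bimodal")`.
#' @param n_species,n_replicates Simulation size per stage and type.
#' @param quota,n_boot Rarefaction quota and bootstrap count.
#' @param do_rarefaction Compute the sampling-standardized treatment?
#' @param window List: `source` (`"synthetic"` or `"collections"`),
#'   synthetic parameters `target_ssc`, `mu`, `sigma`, `p_zero_bin`, or
#'   `collections_path` plus assignment `rule` for real windows. The
#'   special source `"full"` uses the identity window (every
#'   shallow-marine cell sampled).
#' @param geography List: `source` (`"synthetic"` or `"rasters"`),
#'   synthetic `params` ([synthetic_geo_params()]) or `paths` (named by
#'   stage) of ASCII rasters.
#' @param lbg_weights An [lbg_params()] list.
#' @param decay A [decay_params()] list.
#' @param normalize_after_mean Normalise the replicate-mean curve
#'   (default), rather than normalising each replicate before averaging.
#' @param seed Master seed.
#' @param outdir Output directory for CSVs and the manifest; `NULL`
#'   keeps results in memory only.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(stages = NULL,
                              lbg_types = c("flat", "unimodal", "bimodal"),
                              n_species = 1000L, n_replicates = 100L,
                              quota = 50L, n_boot = 1000L,
                              do_rarefaction = TRUE,
                              window = list(source = "synthetic",
                                            target_ssc = 0.7, mu = 37.5,
                                            sigma = 15, p_zero_bin = 0.4),
                              geography = list(source = "synthetic",
                                               params = synthetic_geo_params()),
                              lbg_weights = lbg_params(),
                              decay = decay_params(),
                              normalize_after_mean = TRUE,
                              seed = 1L, outdir = NULL) {
  st <- build_stage_table()
  stages <- if (is.null(stages)) st$name
            else unname(vapply(stages, function(s) stage_bin(s)$name,
                               character(1)))
  bad <- setdiff(lbg_types, c("flat", "unimodal", "bimodal"))
  if (length(bad)) stop("invalid key lbg_types: unknown type '", bad[1], "'")
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop("invalid key n_replicates: must be >= 1")
  if (!is.numeric(quota) || quota < 1)
    stop("invalid key quota: must be >= 1")
  if (!is.list(window) || is.null(window$source) ||
      !window$source %in% c("synthetic", "collections", "full"))
    stop("invalid key window$source: must be 'synthetic', 'collections' or 'full'")
  if (window$source == "collections") {
    if (is.null(window$collections_path))
      stop("invalid key window$collections_path: required for collections windows")
    if (!file.exists(window$collections_path))
      stop("invalid key window$collections_path: file not found: ",
           window$collections_path)
    window$rule <- if (is.null(window$rule)) "midpoint" else window$rule
  }
  if (!is.list(geography) || is.null(geography$source) ||
      !geography$source %in% c("synthetic", "rasters"))
    stop("invalid key geography$source: must be 'synthetic' or 'rasters'")
  if (geography$source == "rasters") {
    if (is.null(geography$paths) ||
        !all(stages %in% names(geography$paths)))
      stop("invalid key geography$paths: a raster path is required for every selected stage")
    absent <- !file.exists(unlist(geography$paths[stages]))
    if (any(absent))
      stop("invalid key geography$paths: file not found: ",
           unlist(geography$paths[stages])[absent][1])
  }
  if (geography$source == "synthetic" && is.null(geography$params))
    geography$params <- synthetic_geo_params()
  structure(list(stages = stages, lbg_types = lbg_types,
                 n_species = as.integer(n_species),
                 n_replicates = as.integer(n_replicates),
                 quota = as.integer(quota), n_boot = as.integer(n_boot),
                 do_rarefaction = isTRUE(do_rarefaction), window = window,
                 geography = geography, lbg_weights = lbg_weights,
                 decay = decay,
                 normalize_after_mean = isTRUE(normalize_after_mean),
                 seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the arguments of [experiment_config()]; unknown
#' keys are rejected by name.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(experiment_config)),
                   c("lbg_weights", "decay"))
  known <- c(known, "lbg_weights", "decay")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("invalid key in config file: '", unknown[1], "'")
  if (!is.null(raw$lbg_weights))
    raw$lbg_weights <- do.call(lbg_params, raw$lbg_weights)
  if (!is.null(raw$decay)) raw$decay <- do.call(decay_params, raw$decay)
  if (!is.null(raw$geography) && identical(raw$geography$source,
                                           "synthetic") &&
      !is.null(raw$geography$params))
    raw$geography$params <- do.call(synthetic_geo_params,
                                    raw$geography$params)
  do.call(experiment_config, raw)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  cfg <- unclass(config)
  cfg$outdir <- NULL  # output location does not change the computation
  writeLines(paste(deparse(cfg), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

.type_index <- function(type) {
  match(type, c("flat", "unimodal", "bimodal"))
}

# geography + window for one stage (shared across LBG types)
.stage_setup <- function(config, stage) {
  dem <- if (config$geography$source == "synthetic") {
    generate_synthetic_dem(stage, config$geography$params,
                           seed = derive_seed(config$seed, 7L))
  } else {
    read_ascii_grid(config$geography$paths[[stage$name]],
                    stage_name = stage$name)
  }
  mask <- shallow_marine_mask(dem)
  window <- switch(config$window$source,
    full = full_window(mask),
    synthetic = generate_synthetic_window(
      mask,
      target_ssc = if (is.null(config$window$target_ssc)) 0.7
                   else config$window$target_ssc,
      mu = if (is.null(config$window$mu)) 37.5 else config$window$mu,
      sigma = if (is.null(config$window$sigma)) 15 else config$window$sigma,
      p_zero_bin = if (is.null(config$window$p_zero_bin)) 0.4
                   else config$window$p_zero_bin,
      seed = derive_seed(config$seed, stage$index, 999L)),
    collections = {
      coll <- read_collections(config$window$collections_path)
      rasterize_window(assign_to_stage(coll, stage,
                                       rule = config$window$rule), mask)
    })
  list(mask = mask, window = window)
}

#' Run the full detectability experiment
#'
#' For every selected stage and LBG type: simulates the assemblage,
#' filters it through the stage's sampling window, computes simulated /
#' sampled (/ sampling-standardized) proportional richness curves,
#' sampling metrics, global richness, pairwise comparisons (each type's
#' simulated curve against its sampled and standardized counterparts,
#' and all type pairs within each treatment) and peak reports. Re-running
#' with an identical config and seed reproduces results bit-identically;
#' with `outdir` set, completed stage-by-type cells found in the cache
#' (keyed by the config hash) are reused rather than recomputed.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_result` with data frames
#'   `curves`, `sampling`, `comparisons`, `global_richness` and a
#'   `manifest` (config, hash, per-cell seeds, errors).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  scheme <- lat_bin_scheme()
  hash <- config_hash(config)
  cache_dir <- NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    cache_dir <- file.path(config$outdir, "cache", hash)
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  }
  treatments <- c("simulated", "sampled",
                  if (config$do_rarefaction) "standardized")
  curves_out <- list(); sampling_out <- list(); comp_out <- list()
  rich_out <- list(); seeds_out <- list(); errors <- character()
  mean_prop <- list()  # [[stage]][[treatment]][[type]] proportional curve

  for (stage_name in config$stages) {
    stage <- stage_bin(stage_name)
    setup <- tryCatch(.stage_setup(config, stage), error = function(e) e)
    if (inherits(setup, "error")) {
      errors <- c(errors, paste0(stage_name, ": ",
                                 conditionMessage(setup)))
      next
    }
    mask <- setup$mask; window <- setup$window
    sampling_out[[stage_name]] <- .sampling_summary(window, mask, scheme)
    mean_prop[[stage_name]] <- list()

    for (type in config$lbg_types) {
      cell <- tryCatch(
        .run_cell(config, stage, mask, window, type, scheme, cache_dir),
        error = function(e) e)
      if (inherits(cell, "error")) {
        errors <- c(errors, paste0(stage_name, " x ", type, ": ",
                                   conditionMessage(cell)))
        next
      }
      key <- paste(stage_name, type, sep = ":")
      curves_out[[key]] <- cell$curves_df
      rich_out[[key]] <- cell$richness_df
      seeds_out[[key]] <- cell$seed
      for (tr in names(cell$prop)) {
        mean_prop[[stage_name]][[tr]][[type]] <- cell$prop[[tr]]
        if (!is.null(cell$prop[[tr]]) && tr != "simulated") {
          comp_out[[paste(key, tr)]] <- compare_curves(
            cell$prop[[tr]], cell$prop$simulated,
            pair_label = paste0(type, ":simulated_vs_", tr))
        }
      }
    }
    # type-pair comparisons within each treatment
    for (tr in treatments) {
      tps <- names(mean_prop[[stage_name]][[tr]])
      if (length(tps) >= 2L) {
        prs <- utils::combn(tps, 2L, simplify = FALSE)
        for (pr in prs) {
          comp_out[[paste(stage_name, tr, pr[1], pr[2])]] <- compare_curves(
            mean_prop[[stage_name]][[tr]][[pr[1]]],
            mean_prop[[stage_name]][[tr]][[pr[2]]],
            pair_label = paste0(tr, ":", pr[1], "_vs_", pr[2]))
        }
      }
    }
  }

  result <- structure(list(
    curves = .rbind_all(curves_out),
    sampling = .rbind_all(sampling_out),
    comparisons = .rbind_all(comp_out),
    global_richness = .rbind_all(rich_out),
    manifest = list(config = unclass(config), hash = hash,
                    seed_scheme = paste(
                      "cell seed = derive_seed(master, stage_index,",
                      "type_index); replicate r reseeds via",
                      "derive_seed(cell_seed, r); window seed =",
                      "derive_seed(master, stage_index, 999)"),
                    cell_seeds = unlist(seeds_out), errors = errors)),
    class = "experiment_result")
  if (!is.null(config$outdir)) .write_result(result, config$outdir)
  result
}

.rbind_all <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (!length(lst)) return(data.frame())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

.sampling_summary <- function(window, mask, scheme) {
  g_ssc <- spatial_sampling_coverage(window, mask, "global")
  b_ssc <- spatial_sampling_coverage(window, mask, "bin", scheme)
  g_mst <- summed_mst_length(window, "global")
  b_mst <- summed_mst_length(window, "bin", scheme)
  ssc <- rbind(g_ssc, b_ssc)
  mst <- rbind(g_mst, b_mst)
  ssc$mst_km <- mst$mst_km[match(ssc$scope, mst$scope)]
  ssc[, c("stage_name", "scope", "ssc_percent", "mst_km", "n_sampled",
          "n_available")]
}

# one stage x type cell: simulate, window, curves
.run_cell <- function(config, stage, mask, window, type, scheme,
                      cache_dir) {
  cell_seed <- derive_seed(config$seed, stage$index, .type_index(type))
  cache_file <- if (!is.null(cache_dir))
    file.path(cache_dir, paste0(stage$name, "_", type, "_occ.csv"))
  occ <- NULL
  if (!is.null(cache_file) && file.exists(cache_file)) {
    occ <- utils::read.csv(cache_file, stringsAsFactors = FALSE)
  } else {
    occ <- simulate_assemblage(stage, mask, type,
                               n_species = config$n_species,
                               n_replicates = config$n_replicates,
                               seed = cell_seed,
                               params = config$lbg_weights,
                               decay = config$decay)
    if (!is.null(cache_file))
      utils::write.csv(occ, cache_file, row.names = FALSE)
  }
  sampled <- apply_window(occ, window)

  reps <- seq_len(config$n_replicates)
  sim_raw <- lapply(reps, function(r) bin_richness_curve(occ, scheme, r))
  smp_raw <- lapply(reps, function(r)
    bin_richness_curve(sampled, scheme, r))
  prop <- list(
    simulated = .mean_proportional(sim_raw, config$normalize_after_mean,
                                   stage$name, scheme),
    sampled = .mean_proportional(smp_raw, config$normalize_after_mean,
                                 stage$name, scheme))
  curves_df <- rbind(
    .treatment_df(prop$simulated, type, "simulated"),
    .treatment_df(prop$sampled, type, "sampled"))
  if (config$do_rarefaction) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    rar <- lapply(reps, function(r) {
      set.seed(derive_seed(cell_seed, r, 31L))
      rarefied_curve(sampled, scheme, quota = config$quota,
                     n_boot = config$n_boot, replicate = r)
    })
    mean_rar <- mean_curve(rar)
    prop$standardized <- if (all(is.na(as.numeric(mean_rar)))) NULL
      else suppressWarnings(normalize_proportional(mean_rar))
    if (!is.null(prop$standardized))
      curves_df <- rbind(curves_df,
                         .treatment_df(prop$standardized, type,
                                       "standardized"))
  }
  richness_df <- data.frame(
    stage_name = stage$name, lbg = type,
    richness_simulated = mean(vapply(reps, function(r)
      global_richness(occ, r), numeric(1))),
    richness_sampled = mean(vapply(reps, function(r)
      global_richness(sampled, r), numeric(1))),
    stringsAsFactors = FALSE)
  list(curves_df = curves_df, richness_df = richness_df, prop = prop,
       seed = cell_seed)
}

.mean_proportional <- function(raw_curves, after_mean, stage_name,
                               scheme) {
  if (after_mean) {
    suppressWarnings(normalize_proportional(mean_curve(raw_curves)))
  } else {
    suppressWarnings(
      mean_curve(lapply(raw_curves, normalize_proportional)))
  }
}

.treatment_df <- function(curve, type, treatment) {
  df <- curve_as_df(curve)
  df$lbg <- type
  df$treatment <- treatment
  df[, c("stage_name", "lbg", "treatment", "bin_label", "value",
         "missing")]
}

.write_result <- function(result, outdir) {
  utils::write.csv(result$curves, file.path(outdir, "curves.csv"),
                   row.names = FALSE)
  utils::write.csv(result$sampling, file.path(outdir, "sampling.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparisons,
                   file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(result$global_richness,
                   file.path(outdir, "global_richness.csv"),
                   row.names = FALSE)
  yaml::write_yaml(result$manifest, file.path(outdir, "manifest.yml"))
  invisible(outdir)
}

#' Summarise an experiment result
#'
#' Produces the four headline summary tables: (i) mean and standard
#' deviation of per-stage displacement series for every pair label;
#' (ii) the fraction of stages whose sampled / standardized curves are
#' statistically different (KS p < 0.05) from their simulated
#' counterparts, per LBG type; (iii) peak bin and zone recovery
#' percentages, per type and treatment; (iv) coefficients of
#' determination between richness and the sampling metrics (SSC and
#' summed MST length).
#'
#' @param result An `experiment_result`.
#' @return A list of data frames: `displacement`, `ks_detectability`,
#'   `peak_recovery`, `richness_vs_sampling`.
#' @export
summarize_results <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  comp <- result$comparisons
  if (!nrow(comp)) stop("empty experiment result")

  displacement <- do.call(rbind, lapply(split(comp, comp$pair_label),
    function(g) data.frame(pair_label = g$pair_label[1],
                           mean_D = mean(g$D, na.rm = TRUE),
                           sd_D = stats::sd(g$D, na.rm = TRUE),
                           n = sum(!is.na(g$D)),
                           stringsAsFactors = FALSE)))
  rownames(displacement) <- NULL

  sv <- comp[grepl(":simulated_vs_", comp$pair_label), , drop = FALSE]
  ks_detectability <- do.call(rbind, lapply(split(sv, sv$pair_label),
    function(g) data.frame(pair_label = g$pair_label[1],
                           n_stages = nrow(g),
                           n_significant = sum(g$ks_p < 0.05,
                                               na.rm = TRUE),
                           frac_significant = mean(g$ks_p < 0.05,
                                                   na.rm = TRUE),
                           stringsAsFactors = FALSE)))
  rownames(ks_detectability) <- NULL

  peak_recovery <- do.call(rbind, lapply(split(sv, sv$pair_label),
    function(g) data.frame(
      pair_label = g$pair_label[1], n_stages = nrow(g),
      pct_peak_bin = 100 * mean(g$peak_bin_test == g$peak_bin_ref,
                                na.rm = TRUE),
      pct_peak_zone = 100 * mean(g$peak_zone_match, na.rm = TRUE),
      stringsAsFactors = FALSE)))
  rownames(peak_recovery) <- NULL

  richness_vs_sampling <- .richness_vs_sampling(result)
  list(displacement = displacement, ks_detectability = ks_detectability,
       peak_recovery = peak_recovery,
       richness_vs_sampling = richness_vs_sampling)
}

.richness_vs_sampling <- function(result) {
  cur <- result$curves; smp <- result$sampling
  if (!nrow(cur) || !nrow(smp)) return(data.frame())
  bins <- smp[smp$scope != "global", , drop = FALSE]
  out <- list()
  for (type in unique(cur$lbg)) for (tr in unique(cur$treatment)) {
    g <- cur[cur$lbg == type & cur$treatment == tr, , drop = FALSE]
    m <- merge(g, bins, by.x = c("stage_name", "bin_label"),
               by.y = c("stage_name", "scope"))
    if (!nrow(m)) next
    for (metric in c("ssc_percent", "mst_km")) {
      rs <- r_squared(m[[metric]], m$value)
      out[[paste(type, tr, metric)]] <- data.frame(
        lbg = type, treatment = tr, metric = metric,
        r_squared = rs$r_squared, p = rs$p, n = rs$n_used,
        stringsAsFactors = FALSE)
    }
  }
  .rbind_all(out)
}
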