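#' Default run configuration
#'
#' A nested list controlling every pipeline stage; YAML-serializable. The
#' `synth` entry makes the run self-contained (inputs generated, then
#' analyzed); replace it with explicit paths to run on prepared files.
#'
#' @param seed Master seed; per-species and per-stage seeds derive from it.
#' @param tpi_radius TPI neighborhood radius.
#' @param n_pseudo Pseudo-absences per species model.
#' @param train_frac,k_folds,n_trees,tune Model-fitting parameters.
#' @param cor_threshold Collinearity screening threshold.
#' @param synth A [synth_config()] or `NULL`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, tpi_radius = 1, n_pseudo = 2000,
                       train_frac = 0.7, k_folds = 10, n_trees = 1000,
                       tune = TRUE, cor_threshold = 0.75,
                       synth = synth_config(seed = seed)) {
  structure(list(seed = as.integer(seed), tpi_radius = tpi_radius,
                 n_pseudo = n_pseudo, train_frac = train_frac,
                 k_folds = k_folds, n_trees = n_trees, tune = tune,
                 cor_threshold = cor_threshold, synth = synth),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with (a subset of) [run_config()]'s fields;
#'   `synth` and `synth$species` entries are mapped onto [synth_config()]
#'   and [species_params()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth
  if (!is.null(synth_args$species))
    synth_args$species <- lapply(synth_args$species, function(sp)
      do.call(species_params, sp))
  if (!is.null(synth_args$n_presence))
    synth_args$n_presence <- unlist(synth_args$n_presence)
  synth <- do.call(synth_config, c(synth_args %||% list(),
                                   if (is.null(synth_args$seed) &&
                                       !is.null(y$seed))
                                     list(seed = as.integer(y$seed))))
  args <- y[setdiff(names(y), "synth")]
  do.call(run_config, c(args, list(synth = synth)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(quiet, fmt, ...) {
  if (!quiet)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes terrain derivation, occurrence preparation (pixel thinning and
#' pseudo-absence sampling), collinearity screening, one random-forest
#' species distribution model per species, binary-map union, and the risk
#' statistics (regional incidence correlation, park ratios, trail overlap,
#' land-cover composition), writing every intermediate artifact plus a
#' machine-readable manifest into `out_dir`. Re-running with the same
#' config reproduces the outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress progress messages.
#' @return Invisible list with the key results: `screening`, `reports`
#'   (per species), `union`, `region_table`, `correlation`, `park_ratios`,
#'   `trail_overlap`, `composition`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  artifacts <- character()
  put_raster <- function(g, name) {
    p <- file.path(out_dir, paste0(name, ".asc"))
    write_raster(g, p)
    artifacts <<- c(artifacts, paste0(name, ".asc"))
    p
  }
  put_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    artifacts <<- c(artifacts, paste0(name, ".csv"))
    p
  }
  put_json <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA)
    artifacts <<- c(artifacts, paste0(name, ".json"))
    p
  }

  log_stage(quiet, "synthgen: generating study system (seed %d)",
            config$synth$seed)
  sys <- gen_study_system(config$synth, tpi_radius = config$tpi_radius)
  stack <- sys$stack
  for (nm in stack$names) put_raster(stack$layers[[nm]], nm)
  write_geojson(lines_to_features(sys$trails),
                file.path(out_dir, "trails.geojson"))
  artifacts <- c(artifacts, "trails.geojson")

  log_stage(quiet, "occurrences: thinning and pseudo-absence sampling")
  species <- names(sys$presences)
  datasets <- list(); thinned <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    thin <- thin_to_pixel(sys$presences[[sp]], stack$spec,
                          seed = config$seed + 200L + i)
    thinned[[sp]] <- thin
    pa <- sample_pseudo_absences(sys$mask, config$n_pseudo,
                                 seed = config$seed + 300L + i,
                                 exclude = thin, species = sp)
    pts <- rbind(thin, pa)
    datasets[[sp]] <- cbind(pts, stack_extract(stack, pts$x, pts$y))
    put_csv(datasets[[sp]], paste0("points_", sp))
  }

  # one screening decision for the whole model set: pooled presences of all
  # species plus a shared pseudo-absence pool
  log_stage(quiet, "screening: collinearity at threshold %g",
            config$cor_threshold)
  pooled_pres <- do.call(rbind, thinned)
  pooled_pa <- sample_pseudo_absences(sys$mask, config$n_pseudo,
                                      seed = config$seed + 390L,
                                      exclude = pooled_pres)
  pooled <- rbind(pooled_pres, pooled_pa)
  screen_data <- cbind(pooled, stack_extract(stack, pooled$x, pooled$y))
  screening <- screen_collinear(screen_data[, stack$names],
                                screen_data$label,
                                threshold = config$cor_threshold)
  write_screening_report(screening,
                         json_path = file.path(out_dir, "screening.json"),
                         csv_path = file.path(out_dir, "screening_correlations.csv"))
  artifacts <- c(artifacts, "screening.json", "screening_correlations.csv")
  retained <- screening$retained

  reports <- list(); binaries <- list()
  for (i in seq_along(species)) {
    sp <- species[i]
    log_stage(quiet, "sdm: fitting %s on {%s}", sp,
              paste(retained, collapse = ", "))
    d <- datasets[[sp]][, c("species", "x", "y", "label", retained)]
    rep_i <- fit_sdm(d, seed = config$seed + 400L + i,
                     n_trees = config$n_trees,
                     train_frac = config$train_frac, k = config$k_folds,
                     tune = config$tune)
    reports[[sp]] <- rep_i
    write_sdm_report(rep_i, file.path(out_dir, paste0("sdm_", sp, ".json")))
    artifacts <- c(artifacts, paste0("sdm_", sp, ".json"))
    surf <- predict_surface(rep_i$model, predictor_stack(stack$layers[retained]))
    put_raster(surf, paste0("suitability_", sp))
    binaries[[sp]] <- binarize(surf, rep_i$threshold)
    put_raster(binaries[[sp]], paste0("binary_", sp))
  }

  log_stage(quiet, "risk: union map and downstream statistics")
  union <- union_maps(binaries)
  put_raster(union, "habitat_union")
  imp <- median_importance(lapply(reports, function(r) r$importance))
  put_csv(imp, "importance_median")

  ri <- gen_regions_and_incidents(union, config$synth)
  put_raster(ri$region_grid, "regions")
  trail_mask <- rasterize_lines(sys$trails, stack$spec)
  put_raster(trail_mask, "trail_mask")
  region_table <- build_region_table(union, ri$region_grid, ri$regions,
                                     trail_mask = trail_mask)
  put_csv(region_table, "region_table")
  correlation <- spearman_test(region_table$habitat_proportion,
                               region_table$incidence_per_10k)

  park_masks <- lapply(seq_along(sys$parks), function(i)
    binarize(rasterize_polygons(sys$parks[i], i, stack$spec), 0.5))
  park_ratios <- vapply(park_masks, function(pm) park_risk_ratio(union, pm),
                        numeric(1))
  park_trail <- vapply(park_masks, function(pm)
    suppressWarnings(trail_overlap(union, trail_mask, pm)), numeric(1))
  put_json(list(park_ratio = park_ratios, park_trail_overlap = park_trail),
           "parks")
  overall_trail <- trail_overlap(union, trail_mask)
  composition <- cover_composition(
    union, predictor_stack(stack$layers[c("forest", "herbaceous")]))

  summary <- list(
    species = lapply(reports, function(r) list(
      auc_train = r$auc_train, auc_test = r$auc_test,
      threshold = r$threshold, tss_train = r$tss_train,
      tss_test = r$tss_test, cv_auc_mean = r$cv$mean %||% NA,
      cv_auc_sd = r$cv$sd %||% NA)),
    retained = retained,
    dropped = screening$dropped,
    habitat_fraction = mean(union$values, na.rm = TRUE),
    spearman_rho = correlation$rho,
    spearman_p = correlation$p_value,
    park_ratios = park_ratios,
    trail_overlap_overall = overall_trail,
    composition = as.list(composition),
    top3_variables = imp$variable[imp$top3])
  put_json(summary, "summary")

  artifacts <- c(artifacts, "manifest.json")
  manifest <- list(
    package = "sdmrisk",
    version = as.character(utils::packageVersion("sdmrisk")),
    seed = config$seed,
    config_hash = config_hash(config),
    species = species,
    n_reports = length(reports),
    artifacts = sort(unique(artifacts)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  put_json(manifest, "manifest")
  log_stage(quiet, "done in %.1f s; %d artifacts",
            manifest$elapsed_sec, length(manifest$artifacts))

  invisible(list(screening = screening, reports = reports, union = union,
                 importance = imp, region_table = region_table,
                 correlation = correlation, park_ratios = park_ratios,
                 trail_overlap = overall_trail, composition = composition,
                 manifest = manifest))
}

# MD5 of the deparsed config (stable across sessions for plain lists).
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}
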