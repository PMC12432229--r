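# Run configuration and end-to-end orchestration: simulate -> composite ->
# train -> predict -> fuse -> analyze -> evaluate, with one global seed
# fanned out deterministically to per-stage seeds and a provenance manifest.

#' Full pipeline configuration
#'
#' Defaults carry the analysis constants: fusion thresholds 0.6 (presence)
#' and 0.5 (shape), water persistence > 0.2, deposit water fraction > 0.2,
#' more than 5 interior holes removed, 10 km hexagonal cells, 512 m
#' evaluation cells, cluster significance 0.002, 95% HDI mass.
#'
#' @param landscape a [landscape_config()].
#' @param model a [seg_model_config()].
#' @param fusion list with `t_presence`, `t_shape`.
#' @param filters list with `water_persistence`, `max_water_fraction`,
#'   `max_holes`.
#' @param grids list with `hex_cell_m`, `eval_cell_m`.
#' @param stats list with `n_permutations`, `cluster_alpha`, `hdi_mass`.
#' @param train list with `n_patches`, `upsample_factor` (bicubic model-input
#'   upsampling; the full-scale configuration uses 3 for 3 m -> 1 m),
#'   `augment_ops`.
#' @param seed global integer seed; every stage seed derives from it.
#' @return A validated `run_config`.
#' @export
run_config <- function(landscape = landscape_config(),
                       model = seg_model_config(),
                       fusion = list(t_presence = 0.6, t_shape = 0.5),
                       filters = list(water_persistence = 0.2,
                                      max_water_fraction = 0.2, max_holes = 5L),
                       grids = list(hex_cell_m = 10000, eval_cell_m = 512),
                       stats = list(n_permutations = 999, cluster_alpha = 0.002,
                                    hdi_mass = 0.95, decay_bin_km = 10),
                       train = list(n_patches = 36L, upsample_factor = 1,
                                    augment_ops = c("flip_vertical", "flip_horizontal")),
                       seed = 1L) {
  cfg <- list(landscape = landscape, model = model, fusion = fusion,
              filters = filters, grids = grids, stats = stats, train = train,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  f <- cfg$fusion
  if (f$t_presence <= 0 || f$t_presence > 1)
    stop_config("t_presence must lie in (0, 1], got %g", f$t_presence)
  if (f$t_shape <= 0 || f$t_shape > 1 || f$t_shape > f$t_presence)
    stop_config("t_shape must lie in (0, t_presence], got %g", f$t_shape)
  fl <- cfg$filters
  if (fl$water_persistence < 0 || fl$water_persistence >= 1)
    stop_config("water_persistence must lie in [0, 1), got %g", fl$water_persistence)
  if (fl$max_water_fraction < 0 || fl$max_water_fraction > 1)
    stop_config("max_water_fraction must lie in [0, 1], got %g", fl$max_water_fraction)
  if (fl$max_holes < 0) stop_config("max_holes must be >= 0")
  if (cfg$grids$hex_cell_m <= 0 || cfg$grids$eval_cell_m <= 0)
    stop_config("grid cell sizes must be positive")
  st <- cfg$stats
  if (st$cluster_alpha <= 0 || st$cluster_alpha > 1)
    stop_config("cluster_alpha must lie in (0, 1], got %g", st$cluster_alpha)
  if (st$hdi_mass <= 0 || st$hdi_mass >= 1)
    stop_config("hdi_mass must lie in (0, 1), got %g", st$hdi_mass)
  validate_landscape_config(cfg$landscape)
  invisible(cfg)
}

#' Load (and validate) a run configuration from YAML
#'
#' Keys absent from the file take their defaults; unknown keys are rejected
#' with the offending name. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- run_config()
  merged <- merge_config(unclass(defaults), user, path = "")
  # rebuild typed sub-configs so their validators run
  if (!is.null(user$landscape)) {
    lc <- merged$landscape
    if (!is.null(user$landscape$river_mouths))
      lc$river_mouths <- as.data.frame(user$landscape$river_mouths)
    merged$landscape <- do.call(landscape_config,
                                lc[names(lc) %in% names(formals(landscape_config))])
  }
  if (!is.null(user$model))
    merged$model <- do.call(seg_model_config,
                            merged$model[names(merged$model) %in% names(formals(seg_model_config))])
  cfg <- merged
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

merge_config <- function(base, user, path) {
  for (nm in names(user)) {
    full <- if (nchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop_config("unknown configuration key: %s", full)
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.data.frame(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], full)
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Save a run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  x <- rapply(unclass(config), function(v) v, how = "replace")
  x$landscape$river_mouths <- as.list(config$landscape$river_mouths)
  x$landscape$spectra <- NULL            # matrices are not YAML-portable; defaults used
  x$landscape$size_lognormal_params <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

config_hash <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  h <- 0
  for (k in utf8ToInt(txt)) h <- (h * 131 + k) %% 2^28
  sprintf("%07x", h)
}

#' A small desk-scale configuration for complete pipeline runs
#'
#' A 3 x 1.5 km tile at 3 m with a 1 m aerial reference, elevated deposit
#' densities so a scene holds enough deposits to train on, well-separated
#' spectra (high SNR), a compact 2-level U-Net on 64 px patches, and a 500 m
#' hexagonal cell so the tile spans enough cells for spatial statistics.
#' These are the scaled-down study conditions used throughout the package's
#' end-to-end examples and checks.
#'
#' @param seed global seed.
#' @return A `run_config`.
#' @export
desk_run_config <- function(seed = 1L) {
  run_config(
    landscape = landscape_config(
      extent_m = c(3072, 1536),
      pixel_size_m = list(satellite = 3, aerial = 1, reference = 30),
      river_mouths = data.frame(x = c(500, 1600, 2700),
                                forest_fraction = c(0.9, 0.5, 0.2)),
      cluster_density_per_km2 = 40, background_density_per_km2 = 8,
      cluster_radius_km = 1.2, delta_radius_km = 0.25,
      aerial_log_density_per_km2 = 150,
      noise_sd = 0.015, shore_wavelength_m = 1600,
      seed = seed),
    model = seg_model_config(input_bands = 5L, depth = 2L, base_filters = 8L,
                             patch_size = 64L, epochs = 22L, batch_size = 8L,
                             learning_rate = 0.01, seed = seed),
    grids = list(hex_cell_m = 500, eval_cell_m = 512),
    stats = list(n_permutations = 199, cluster_alpha = 0.05, hdi_mass = 0.95,
                 decay_bin_km = 0.2),
    train = list(n_patches = 48L, upsample_factor = 1,
                 augment_ops = c("flip_vertical", "flip_horizontal")),
    seed = seed)
}

stage <- function(name, code) {
  tryCatch(force(code),
           error = function(e) stop(sprintf("pipeline stage '%s' failed: %s",
                                            name, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' simulate -> composite (per year) -> train -> predict (per year) -> fuse ->
#' analyze -> evaluate, writing all artifacts and a provenance manifest into
#' `out_dir`. Rerunning with the same seed reproduces deterministic outputs
#' exactly. A stage failure aborts with the stage name; artifacts of earlier
#' stages are retained.
#'
#' @param config a [run_config()] (see [desk_run_config()] for a small one).
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return Invisibly, a list with the main in-memory results (`truth`,
#'   `fit`, `deposits`, `hex`, `stats`, `eval`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  lcfg <- config$landscape
  lcfg$seed <- derive_seed(config$seed, "simulate")
  mcfg <- config$model
  mcfg$seed <- derive_seed(config$seed, "model")

  say("stage simulate")
  truth <- stage("simulate", {
    tr <- generate_landscape(lcfg)
    write_truth(tr, file.path(out_dir, "truth"))
    tr
  })

  say("stage composite")
  composites <- stage("composite", {
    ref <- render_reference(truth, lcfg)
    comps <- lapply(seq_len(lcfg$n_years), function(y) {
      scenes <- render_scenes(truth, y, lcfg)
      comp <- build_annual_composite(scenes, ref)
      comp <- stack_elevation(comp, truth$dem)
      write_raster(comp, file.path(out_dir, sprintf("composite_year%d", y)))
      comp
    })
    write_raster(ref, file.path(out_dir, "reference"))
    comps
  })

  # per-band z-score normalisation: reflectance and elevation live on very
  # different scales; standardising the model inputs conditions the first
  # convolution (each year normalised with its own statistics -- the
  # composites share a histogram-matching reference, so these agree closely)
  normalize_bands <- function(comp) {
    for (b in seq_len(raster_nband(comp))) {
      v <- comp$values[, , b]
      mu <- mean(v, na.rm = TRUE); sd <- stats::sd(v, na.rm = TRUE)
      comp$values[, , b] <- (v - mu) / max(sd, 1e-9)
    }
    comp
  }
  norm_composites <- lapply(composites, normalize_bands)

  say("stage train")
  fit <- stage("train", {
    labels <- raster_band(truth$class_maps[[1]], 1) == CLASS_WOOD
    comp <- norm_composites[[1]]
    if (config$train$upsample_factor > 1) {
      comp <- upsample_bicubic(comp, config$train$upsample_factor)
      lab_r <- upsample_bicubic(mb_raster(labels * 1, xmin = 0,
                                          ymax = lcfg$extent_m[2],
                                          pixel_size = truth_pixel_size(lcfg)),
                                config$train$upsample_factor, labels = TRUE)
      labels <- raster_band(lab_r, 1) > 0
    }
    # stratified sampling: half the patches from the coastal band (where
    # deposits occur), half from the full tile so every land-cover class is
    # represented at prediction time
    shore <- shore_y_fun(lcfg)
    band_rows <- which(raster_coords(comp)$y <
                         max(shore(seq(0, lcfg$extent_m[1], by = 50))) + 50)
    r0 <- max(1L, min(band_rows) - 10L)
    r1 <- min(raster_nrow(comp), r0 + max(config$model$patch_size + 2L,
                                          ceiling(lcfg$band_width_m / comp$pixel_size) + 20L))
    # two coastal strata against one full-tile stratum: two thirds of the
    # patches see deposits, one third covers the remaining land-cover classes
    areas <- data.frame(name = c("coastal_band", "coastal_band2", "full_tile"),
                        row0 = c(r0, r0, 1L), col0 = 1L,
                        row1 = c(r1, r1, raster_nrow(comp)),
                        col1 = raster_ncol(comp))
    patches <- sample_patches(comp, labels, config$train$n_patches,
                              config$model$patch_size,
                              seed = derive_seed(config$seed, "patches"),
                              areas = areas)
    sp <- split_areas(seq_along(patches), c(0.6, 0.2, 0.2),
                      seed = derive_seed(config$seed, "split"))
    # the validation loss must see the positive class: if the draw left the
    # validation set without any driftwood patch, swap one in from training
    has_pos <- vapply(patches, function(p) any(p$y > 0), TRUE)
    if (!any(has_pos[sp$val]) && any(has_pos[sp$train])) {
      give <- sp$train[which(has_pos[sp$train])[1]]
      take <- sp$val[1]
      sp$train <- c(setdiff(sp$train, give), take)
      sp$val <- c(setdiff(sp$val, take), give)
    }
    train_p <- patches[sp$train]
    if (length(config$train$augment_ops))
      train_p <- c(train_p, unlist(lapply(seq_along(train_p), function(i)
        augment(train_p[[i]], config$train$augment_ops,
                seed = derive_seed(config$seed, paste0("augment", i)))),
        recursive = FALSE))
    model <- build_unet(mcfg)
    train_unet(model, train_p, patches[sp$val], test_patches = patches[sp$test],
               config = mcfg, verbose = verbose)
  })

  say("stage predict")
  binaries <- stage("predict", {
    lapply(seq_len(lcfg$n_years), function(y) {
      pr <- predict_tiled(fit, norm_composites[[y]], mcfg)
      write_raster(pr$binary, file.path(out_dir, sprintf("prediction_year%d", y)))
      pr$binary
    })
  })

  say("stage fuse")
  fused <- stage("fuse", {
    prob <- presence_probability(binaries)
    dep <- extract_deposits(prob, config$fusion$t_presence, config$fusion$t_shape)
    wmask <- build_water_mask(truth$water_masks, config$filters$water_persistence)
    infra <- raster_band(truth$class_maps[[1]], 1) == CLASS_INFRA
    fl <- filter_deposits(dep, wmask, infra,
                          config$filters$max_water_fraction, config$filters$max_holes)
    write_raster(prob, file.path(out_dir, "presence_probability"))
    write_deposits(fl$deposits, file.path(out_dir, "deposits.geojson"))
    utils::write.csv(fl$removed, file.path(out_dir, "removal_log.csv"),
                     row.names = FALSE)
    fl
  })
  deposits <- fused$deposits

  say("stage analyze")
  ana <- stage("analyze", {
    res <- list(flags = character(0))
    grid <- make_hex_grid(c(0, lcfg$extent_m[1], 0, lcfg$extent_m[2]),
                          config$grids$hex_cell_m)
    land <- raster_band(truth$class_maps[[1]], 1) != CLASS_WATER
    grid <- aggregate_to_grid(deposits, grid,
                              mb_raster(land * 1, xmin = 0, ymax = lcfg$extent_m[2],
                                        pixel_size = truth_pixel_size(lcfg)))
    res$grid <- grid
    vals <- grid$stats$cover_fraction
    vals[is.na(vals)] <- 0
    if (nrow(deposits$table) == 0) {
      res$flags <- c(res$flags, "no_deposits")
    } else if (stats::var(vals) > 0 && length(vals) >= 3) {
      res$global_moran <- global_morans_i(vals, grid$nb,
                                          config$stats$n_permutations,
                                          seed = derive_seed(config$seed, "moran"))
      res$local_moran <- local_morans_i(vals, grid$nb,
                                        config$stats$n_permutations,
                                        alpha = config$stats$cluster_alpha,
                                        seed = derive_seed(config$seed, "lisa"))
      cl_cells <- unlist(res$local_moran$clusters)
      in_cl <- rep(FALSE, nrow(deposits$table))
      if (length(cl_cells)) {
        cid <- hex_locate(grid, deposits$table$x, deposits$table$y)
        in_cl <- cid %in% cl_cells
      }
      if (any(in_cl) && any(!in_cl)) {
        res$size_mwu <- mann_whitney_u(deposits$table$area_m2[in_cl],
                                       deposits$table$area_m2[!in_cl])
        res$size_best <- best_bayes_compare(deposits$table$area_m2[in_cl],
                                            deposits$table$area_m2[!in_cl],
                                            seed = derive_seed(config$seed, "best"))
      } else res$flags <- c(res$flags, "no_cluster_contrast")
    } else res$flags <- c(res$flags, "constant_cover_field")
    if (nrow(deposits$table) > 0 && nrow(truth$mouths) > 0) {
      asg <- assign_catchments(deposits, truth$catchments)
      per_catch <- tapply(asg$area_m2, asg$source_catchment_id, sum)
      ff <- truth$catchments$forest_fraction[match(as.integer(names(per_catch)),
                                                   truth$catchments$id)]
      if (length(per_catch) >= 3) {
        res$forest_spearman <- spearman_rho(ff, as.numeric(per_catch))
        res$forest_bayes <- bayes_correlation(ff, as.numeric(per_catch))
      } else res$flags <- c(res$flags, "too_few_catchments")
      dd <- distance_decay(deposits, truth$mouths[truth$mouths$forest_fraction > 0, ],
                           bin_km = config$stats$decay_bin_km %||% 10)
      res$decay <- dd
      nz <- dd$binned
      if (nrow(nz) >= 3 && stats::var(nz$area_m2) > 0) {
        res$decay_spearman <- spearman_rho(nz$d_mid_km, nz$area_m2)
      }
    }
    out <- list(flags = res$flags)
    if (!is.null(res$global_moran))
      out$global_moran <- list(I = res$global_moran$statistic,
                               pseudo_p = res$global_moran$p_value)
    if (!is.null(res$local_moran))
      out$n_clusters <- length(res$local_moran$clusters)
    if (!is.null(res$size_mwu))
      out$size_mwu <- list(U = res$size_mwu$statistic, p = res$size_mwu$p_value)
    if (!is.null(res$size_best))
      out$size_best <- list(bf10 = res$size_best$bayes_factor_10,
                            hdi = c(res$size_best$hdi_low, res$size_best$hdi_high))
    if (!is.null(res$forest_spearman))
      out$forest_spearman <- list(rho = res$forest_spearman$statistic,
                                  p = res$forest_spearman$p_value)
    if (!is.null(res$decay_spearman))
      out$decay_spearman <- list(rho = res$decay_spearman$statistic,
                                 p = res$decay_spearman$p_value)
    if (!is.null(res$decay))
      out$fraction_within_200km <- res$decay$fraction_within(200)
    jsonlite::write_json(out, file.path(out_dir, "statistics.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(cbind(grid$cells, grid$stats[, -1]),
                     file.path(out_dir, "hex_statistics.csv"), row.names = FALSE)
    res
  })

  say("stage evaluate")
  ev <- stage("evaluate", {
    aerial_cm <- build_class_map(truth, lcfg$pixel_size_m$aerial, 1L)
    ref_dep <- vectorize_and_measure(raster_band(aerial_cm, 1) == CLASS_WOOD,
                                     aerial_cm)
    er <- grid_compare(deposits, ref_dep, config$grids$eval_cell_m)
    sb <- size_stratified_bias(deposits, ref_dep)
    jsonlite::write_json(list(r_squared = er$r_squared, slope = er$slope,
                              relative_bias_percent = er$relative_bias_percent,
                              relative_bias_excl_small_percent = er$relative_bias_excl_small_percent,
                              n_cells = er$n_cells, flags = er$flags,
                              share_below_first_edge = attr(sb, "share_below_first_edge")),
                         file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(sb, file.path(out_dir, "size_stratified_bias.csv"),
                     row.names = FALSE)
    list(report = er, stratified = sb, reference = ref_dep)
  })

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stage_seeds = list(simulate = lcfg$seed, model = mcfg$seed),
                   n_deposits = nrow(deposits$table),
                   started = format(t_start), finished = format(Sys.time()),
                   r_version = as.character(getRversion()))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(truth = truth, fit = fit, deposits = deposits,
                 composites = composites, binaries = binaries,
                 analysis = ana, eval = ev, out_dir = out_dir))
}
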