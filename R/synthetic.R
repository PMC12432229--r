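# Synthetic coastal landscape generator. Produces vector ground truth
# (driftwood deposit polygons, catchments, river mouths, infrastructure) and
# categorical truth rasters from which multi-scene, multi-year imagery is
# rendered. The statistical structure mirrors what the analysis assumes:
# lognormal deposit sizes that differ between deltaic / coastal-cluster /
# background settings, exponential distance decay of deposits from their
# source river mouth, source weighting by catchment forest cover, and
# inter-annual remobilisation so only a fraction of deposits persists through
# all years.

CLASS_WATER <- 1L; CLASS_SAND <- 2L; CLASS_VEG <- 3L
CLASS_WOOD <- 4L; CLASS_INFRA <- 5L
CLASS_NAMES <- c("water", "sand", "vegetation", "driftwood", "infrastructure")

default_spectra <- function() {
  # band means (B, G, R, NIR) per class; driftwood is separated from sand
  # mainly by NIR contrast, with noise overlap keeping segmentation non-trivial
  m <- rbind(
    water          = c(0.06, 0.07, 0.05, 0.02),
    sand           = c(0.26, 0.31, 0.36, 0.42),
    vegetation     = c(0.05, 0.12, 0.08, 0.45),
    driftwood      = c(0.20, 0.22, 0.24, 0.18),
    infrastructure = c(0.30, 0.30, 0.31, 0.24))
  colnames(m) <- c("B", "G", "R", "NIR")
  m
}

lognormal_from_mean <- function(mean_m2, sdlog) {
  c(meanlog = log(mean_m2) - sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration of a synthetic coastal landscape
#'
#' Defaults encode the generative counterparts of the structure the analysis
#' expects: mean deposit sizes of about 1,024 m2 (deltaic), 2,670 m2
#' (coastal cluster) and 1,031 m2 (background); agglomeration densities of
#' 0.85 per km2 in cluster zones versus 0.16 outside; an exponential
#' distance-decay scale of 112 km (so about 83% of deposit area falls within
#' 200 km of a source mouth); and a remobilisation probability of 0.79, i.e.
#' roughly one deposit in five persists through all years while the rest are
#' seen in n_years - 1 of the years.
#'
#' @param extent_m numeric `c(width, height)` of the tile in metres. The coast
#'   runs along x; the sea occupies the top of the tile.
#' @param pixel_size_m list with `satellite`, `aerial`, `reference` (and
#'   optionally `truth`) pixel sizes in metres. Truth rasters default to the
#'   satellite resolution.
#' @param n_years number of annual epochs.
#' @param n_scenes_per_year number of overlapping scene footprints per year.
#' @param river_mouths data.frame with columns `x` (alongshore position, m)
#'   and `forest_fraction` in `[0,1]`; 0 marks a non-forested catchment.
#' @param decay_scale_km scale of the exponential alongshore distance of a
#'   deposit from its assigned mouth.
#' @param size_lognormal_params list of `c(meanlog, sdlog)` per setting
#'   (`deltaic`, `coastal_cluster`, `background`).
#' @param cluster_density_per_km2,background_density_per_km2 expected deposit
#'   counts per km2 of the coastal deposition band, inside and outside
#'   cluster zones.
#' @param cluster_radius_km,delta_radius_km alongshore half-widths defining
#'   the coastal-cluster and deltaic zones around each mouth.
#' @param band_width_m cross-shore width of the deposition (beach) band.
#' @param remobilization_prob probability that a deposit does NOT persist
#'   through all years.
#' @param spectra class-by-band matrix of reflectance means.
#' @param noise_sd per-pixel Gaussian noise of satellite scenes.
#' @param aerial_noise_sd per-pixel noise of the aerial render.
#' @param scene_gain_sd,scene_offset_sd radiometric jitter (multiplicative /
#'   additive, per scene and band) that histogram matching must remove.
#' @param aerial_log_density_per_km2 density of individual stranded logs
#'   (small elongated polygons below the satellite minimum mapping unit).
#' @param shore_amp_m,shore_wavelength_m,shore_jitter_m shoreline geometry:
#'   sinusoidal amplitude/wavelength and per-year vertical jitter.
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated `landscape_config` object (a list).
#' @export
landscape_config <- function(extent_m = c(12000, 4200),
                             pixel_size_m = list(satellite = 3, aerial = 0.2, reference = 30),
                             n_years = 3L,
                             n_scenes_per_year = 3L,
                             river_mouths = data.frame(
                               x = c(2000, 6000, 10000),
                               forest_fraction = c(0.85, 0.45, 0.15)),
                             decay_scale_km = 112,
                             size_lognormal_params = list(
                               deltaic = lognormal_from_mean(1024, 1.1),
                               coastal_cluster = lognormal_from_mean(2670, 1.3),
                               background = lognormal_from_mean(1031, 1.1)),
                             cluster_density_per_km2 = 0.85,
                             background_density_per_km2 = 0.16,
                             cluster_radius_km = 20,
                             delta_radius_km = 3,
                             band_width_m = 300,
                             remobilization_prob = 0.79,
                             spectra = default_spectra(),
                             noise_sd = 0.02,
                             aerial_noise_sd = 0.02,
                             scene_gain_sd = 0.05,
                             scene_offset_sd = 0.02,
                             aerial_log_density_per_km2 = 30,
                             shore_amp_m = 80,
                             shore_wavelength_m = 6000,
                             shore_jitter_m = 6,
                             seed = 1L) {
  cfg <- list(extent_m = as.numeric(extent_m), pixel_size_m = pixel_size_m,
              n_years = as.integer(n_years),
              n_scenes_per_year = as.integer(n_scenes_per_year),
              river_mouths = river_mouths, decay_scale_km = decay_scale_km,
              size_lognormal_params = size_lognormal_params,
              cluster_density_per_km2 = cluster_density_per_km2,
              background_density_per_km2 = background_density_per_km2,
              cluster_radius_km = cluster_radius_km,
              delta_radius_km = delta_radius_km,
              band_width_m = band_width_m,
              remobilization_prob = remobilization_prob,
              spectra = spectra, noise_sd = noise_sd,
              aerial_noise_sd = aerial_noise_sd,
              scene_gain_sd = scene_gain_sd, scene_offset_sd = scene_offset_sd,
              aerial_log_density_per_km2 = aerial_log_density_per_km2,
              shore_amp_m = shore_amp_m, shore_wavelength_m = shore_wavelength_m,
              shore_jitter_m = shore_jitter_m, seed = as.integer(seed))
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
  cfg
}

#' Large-extent coastal study configuration
#'
#' A 1,200 km coastline with six river mouths of graded catchment forest
#' cover, the 112 km exponential decay scale, and deposit densities scaled so
#' a single run yields on the order of ten thousand deposits -- the scale at
#' which the distributional properties of the generator (distance-decay CDF,
#' forest-cover/deposit-cover correlation, hotspot structure) can be measured
#' tightly. Truth rasters use a 200 m grid; imagery is never rendered at this
#' extent.
#'
#' @param seed integer seed.
#' @return A [landscape_config()].
#' @export
coastal_study_config <- function(seed = 1L) {
  landscape_config(
    extent_m = c(1.2e6, 4200),
    pixel_size_m = list(satellite = 3, aerial = 1, reference = 30, truth = 200),
    river_mouths = data.frame(
      x = c(2e5, 3.5e5, 5e5, 6.5e5, 8e5, 1e6),
      forest_fraction = c(0.9, 0.7, 0.55, 0.4, 0.25, 0.12)),
    decay_scale_km = 112,
    cluster_density_per_km2 = 60, background_density_per_km2 = 22,
    aerial_log_density_per_km2 = 0, shore_amp_m = 0, seed = seed)
}

#' Single-source distance-decay study configuration
#'
#' One river mouth at the centre of a 1,200 km coastline, so the distance to
#' the nearest mouth IS the drawn alongshore distance and the empirical
#' area-weighted decay can be compared against the closed-form exponential
#' CDF (the coast truncates the exponential at 600 km, which shifts the
#' 200 km fraction by under half a percentage point).
#'
#' @param seed integer seed.
#' @return A [landscape_config()].
#' @export
decay_study_config <- function(seed = 1L) {
  landscape_config(
    extent_m = c(1.2e6, 4200),
    pixel_size_m = list(satellite = 3, aerial = 1, reference = 30, truth = 200),
    river_mouths = data.frame(x = 6e5, forest_fraction = 0.9),
    decay_scale_km = 112,
    cluster_density_per_km2 = 60, background_density_per_km2 = 29,
    aerial_log_density_per_km2 = 0, shore_amp_m = 0, seed = seed)
}

validate_landscape_config <- function(cfg) {
  if (length(cfg$extent_m) != 2L || any(cfg$extent_m <= 0))
    stop_config("extent_m must be two positive numbers (width, height)")
  for (nm in c("satellite", "aerial", "reference")) {
    ps <- cfg$pixel_size_m[[nm]]
    if (is.null(ps) || ps <= 0) stop_config("pixel_size_m$%s must be positive", nm)
  }
  ps <- cfg$pixel_size_m$satellite
  if (any(abs(cfg$extent_m / ps - round(cfg$extent_m / ps)) > 1e-6))
    stop_config("satellite pixel size (%g m) must divide the extent", ps)
  if (cfg$decay_scale_km <= 0) stop_config("decay_scale_km must be > 0")
  if (cfg$remobilization_prob < 0 || cfg$remobilization_prob > 1)
    stop_config("remobilization_prob must lie in [0,1]")
  if (cfg$n_years < 1L) stop_config("n_years must be >= 1")
  if (cfg$n_scenes_per_year < 1L) stop_config("n_scenes_per_year must be >= 1")
  dens <- cfg$cluster_density_per_km2 + cfg$background_density_per_km2
  if (dens > 0 && nrow(cfg$river_mouths) == 0L)
    stop_config("deposits requested but river_mouths is empty")
  if (any(cfg$river_mouths$forest_fraction < 0 | cfg$river_mouths$forest_fraction > 1))
    stop_config("forest_fraction must lie in [0,1]")
  invisible(cfg)
}

truth_pixel_size <- function(cfg) cfg$pixel_size_m$truth %||% cfg$pixel_size_m$satellite

shore_y_fun <- function(cfg) {
  base <- 0.75 * cfg$extent_m[2]
  function(x) base + cfg$shore_amp_m * sin(2 * pi * x / cfg$shore_wavelength_m)
}

ellipse_ring <- function(cx, cy, a, b, theta, n = 24L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ex <- a * cos(t); ey <- b * sin(t)
  cbind(cx + ex * cos(theta) - ey * sin(theta),
        cy + ex * sin(theta) + ey * cos(theta))
}

#' Generate a synthetic landscape with ground truth
#'
#' Runs the full generative model: shoreline and digital elevation model,
#' per-year water and land-cover class maps, driftwood deposits placed by an
#' exponential alongshore distance draw from a source mouth (chosen with
#' probability proportional to catchment forest cover), lognormal sizes per
#' setting, berm/mat shapes, individual sub-pixel logs, catchments,
#' infrastructure, and a persistence flag per deposit. Deterministic for a
#' fixed `config$seed`.
#'
#' Deposit polygons are pixel-exact: each deposit's stored polygon follows the
#' pixel boundaries of its rasterisation at truth resolution, so the shoelace
#' polygon area equals pixel count times pixel area by construction.
#'
#' @param config a [landscape_config()].
#' @param build_rasters build the per-year class maps and water masks
#'   (default TRUE). Distribution-scale studies that only need the vector
#'   truth (deposit table, catchments, mouths) can skip them.
#' @return An object of class `scene_truth`.
#' @export
generate_landscape <- function(config, build_rasters = TRUE) {
  validate_landscape_config(config)
  with_seed(derive_seed(config$seed, "generate_landscape"), {
    W <- config$extent_m[1]; H <- config$extent_m[2]
    ps <- truth_pixel_size(config)
    ncols <- round(W / ps); nrows <- round(H / ps)
    template <- mb_raster(matrix(0L, nrows, ncols), xmin = 0, ymax = H,
                          pixel_size = ps, bands = "class")
    shore <- shore_y_fun(config)

    # coastline polyline, sampled finely enough for arclength work
    step <- max(min(50, W / 200), ps)
    cx <- seq(0, W, by = step)
    coastline <- cbind(cx, shore(cx))
    cs <- polyline_length(coastline)
    L <- cs[length(cs)]

    # mouths and catchments (vertical strips split at inter-mouth midpoints)
    mouths <- config$river_mouths
    n_mouth <- nrow(mouths)
    mouth_s <- if (n_mouth) project_to_polyline(mouths$x, shore(mouths$x), coastline)$s else numeric(0)
    catchments <- NULL
    if (n_mouth) {
      ord <- order(mouths$x)
      mouths <- mouths[ord, , drop = FALSE]
      mouth_s <- mouth_s[ord]
      bounds <- c(0, if (n_mouth > 1) (mouths$x[-n_mouth] + mouths$x[-1]) / 2, W)
      catchments <- data.frame(id = seq_len(n_mouth), x_min = bounds[-(n_mouth + 1L)],
                               x_max = bounds[-1], forest_fraction = mouths$forest_fraction,
                               outlet_s = mouth_s)
      mouths$id <- seq_len(n_mouth)
      mouths$y <- shore(mouths$x)
      mouths$s <- mouth_s
    }

    # per-year shoreline jitter (remobilising water line)
    year_jitter <- if (config$n_years > 1) stats::rnorm(config$n_years, 0, config$shore_jitter_m) else 0

    # ---- deposits -------------------------------------------------------
    band_w <- min(config$band_width_m, 0.5 * H)
    dens_total <- config$cluster_density_per_km2 + config$background_density_per_km2
    deposits <- NULL; polys <- list(); years_list <- list()
    if (dens_total > 0 && n_mouth > 0) {
      clus_r <- config$cluster_radius_km * 1000
      in_cluster_zone <- function(s) {
        out <- rep(FALSE, length(s))
        for (ms in mouth_s) out <- out | abs(s - ms) <= clus_r
        out
      }
      in_delta_zone <- function(s) {
        out <- rep(FALSE, length(s))
        for (ms in mouth_s) out <- out | abs(s - ms) <= config$delta_radius_km * 1000
        out
      }
      sgrid <- seq(0, L, by = max(L / 2000, 1))
      frac_cluster <- mean(in_cluster_zone(sgrid))
      band_area_km2 <- (L / 1000) * (band_w / 1000)
      n_dep <- stats::rpois(1, band_area_km2 *
                              (frac_cluster * config$cluster_density_per_km2 +
                               (1 - frac_cluster) * config$background_density_per_km2))
      if (n_dep > 0) {
        w <- mouths$forest_fraction
        if (sum(w) <= 0) w <- rep(1, n_mouth)
        src <- sample.int(n_mouth, n_dep, replace = TRUE, prob = w)
        # alongshore position: signed exponential from the mouth, resampled
        # until it falls on the coastline
        s_pos <- numeric(n_dep)
        for (i in seq_len(n_dep)) {
          repeat {
            d <- stats::rexp(1, rate = 1 / (config$decay_scale_km * 1000)) *
              sample(c(-1, 1), 1)
            s <- mouth_s[src[i]] + d
            if (s >= 0 && s <= L) { s_pos[i] <- s; break }
          }
        }
        setting <- ifelse(in_delta_zone(s_pos), "deltaic",
                          ifelse(in_cluster_zone(s_pos), "coastal_cluster", "background"))
        sizes <- vapply(setting, function(st) {
          p <- config$size_lognormal_params[[st]]
          min(stats::rlnorm(1, p["meanlog"], p["sdlog"]), 5e4)
        }, 0)
        is_berm <- stats::runif(n_dep) < 0.6
        aspect <- ifelse(is_berm, stats::runif(n_dep, 4, 8), stats::runif(n_dep, 1, 1.6))
        a <- sqrt(sizes * aspect / pi)
        b <- sizes / (pi * a)
        # clamp the cross-shore semi-axis into the band
        over <- b > (band_w - 20) / 2
        if (any(over)) {
          b[over] <- (band_w - 20) / 2
          a[over] <- sizes[over] / (pi * b[over])
        }
        # alongshore separation, applied only while the coast has capacity:
        # nudging a dense packing would pile deposits up sequentially and
        # destroy the exponential distance structure, so when total demand
        # exceeds 60% of the coast, deposits are left where they were drawn
        # and overlaps are tolerated (they merge into larger agglomerations)
        margin_sep <- 2 * min(ps, 5)
        if (sum(2 * a + margin_sep) <= 0.6 * L) {
          ord <- order(s_pos)
          last_end <- -Inf
          for (k in ord) {
            lo <- s_pos[k] - a[k] - margin_sep
            if (lo <= last_end) {
              cand <- last_end + a[k] + margin_sep
              if (cand + a[k] <= L) s_pos[k] <- cand
            }
            last_end <- max(last_end, s_pos[k] + a[k] + margin_sep)
          }
        }
        idx <- seq_len(n_dep)
        margin <- 3 * config$shore_jitter_m + 6
        persistent <- stats::runif(n_dep) >= config$remobilization_prob
        dep_rows <- list(); di <- 0L
        for (k in idx) {
          # map alongshore position back to the coastline
          xk <- stats::approx(cs, coastline[, 1], xout = s_pos[k])$y
          yshore <- shore(xk)
          depth_max <- band_w - 2 * b[k] - margin
          off <- b[k] + margin + if (depth_max > 0) stats::runif(1, 0, depth_max) else 0
          cyk <- yshore - off
          tang <- atan2(shore(xk + 1) - shore(xk - 1), 2)
          ring <- ellipse_ring(xk, cyk, a[k], b[k], tang)
          ring[, 1] <- pmin(pmax(ring[, 1], ps), W - ps)
          burn <- rasterize_polygons(list(list(ring)), template, values = 1L)
          cells <- which(burn == 1L)
          if (!length(cells)) { # sub-pixel deposit: burn the centre pixel
            rc <- world_to_pixel(template, xk, cyk)
            if (any(is.na(rc))) next
            cells <- (rc[1, "col"] - 1L) * nrows + rc[1, "row"]
          }
          rc <- arrayInd(cells, c(nrows, ncols))
          r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
          sub <- matrix(FALSE, max(rc[, 1]) - r0 + 1L, max(rc[, 2]) - c0 + 1L)
          sub[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- TRUE
          subtpl <- mb_raster(matrix(0L, nrow(sub), ncol(sub)),
                              xmin = (c0 - 1L) * ps, ymax = H - (r0 - 1L) * ps,
                              pixel_size = ps)
          pring <- component_polygon(sub, subtpl)
          di <- di + 1L
          yrs <- if (persistent[k] || config$n_years == 1L) seq_len(config$n_years)
                 else sort(sample.int(config$n_years, max(1L, config$n_years - 1L)))
          dep_rows[[di]] <- data.frame(
            id = di, setting = setting[k], mouth_id = mouths$id[src[k]],
            persistent = persistent[k] && config$n_years > 1L,
            size_m2 = sizes[k], area_m2 = length(cells) * ps^2,
            x = xk, y = cyk, s_alongshore = s_pos[k],
            dist_to_mouth_km = abs(s_pos[k] - mouth_s[src[k]]) / 1000,
            n_pixels = length(cells))
          polys[[di]] <- pring
          years_list[[di]] <- yrs
          attr(polys[[di]], "cells") <- cells
        }
        if (di > 0L) { deposits <- do.call(rbind, dep_rows); rownames(deposits) <- NULL }
      }
    }
    if (is.null(deposits))
      deposits <- data.frame(id = integer(0), setting = character(0),
                             mouth_id = integer(0), persistent = logical(0),
                             size_m2 = numeric(0), area_m2 = numeric(0),
                             x = numeric(0), y = numeric(0),
                             s_alongshore = numeric(0),
                             dist_to_mouth_km = numeric(0), n_pixels = integer(0))

    # ---- individual logs (below the satellite minimum mapping unit) -----
    logs <- list()
    n_logs <- stats::rpois(1, config$aerial_log_density_per_km2 * (L / 1000) * (band_w / 1000))
    if (n_logs > 0) {
      sl <- stats::runif(n_logs, 0, L)
      for (i in seq_len(n_logs)) {
        xk <- stats::approx(cs, coastline[, 1], xout = sl[i])$y
        yk <- shore(xk) - stats::runif(1, 30, band_w - 10)
        len <- stats::runif(1, 3, 10); wid <- stats::runif(1, 0.3, 0.8)
        logs[[i]] <- ellipse_ring(xk, yk, len / 2, wid / 2,
                                  stats::runif(1, 0, pi), n = 12L)
      }
    }

    # ---- infrastructure -------------------------------------------------
    road_y <- 0.75 * H - band_w - 200
    road <- cbind(seq(0, W, length.out = 40), road_y + 30 * sin(seq(0, 3 * pi, length.out = 40)))
    attr(road, "type") <- "LineString"
    buildings <- list()
    if (n_mouth) {
      bx <- mouths$x[1]
      for (k in 1:3) {
        x0 <- bx + 60 * k; y0 <- road_y - 80 - 10 * k
        buildings[[k]] <- cbind(c(x0, x0 + 20, x0 + 20, x0), c(y0, y0, y0 + 20, y0 + 20))
      }
    }

    # ---- DEM ------------------------------------------------------------
    cc <- raster_coords(template)
    ydist <- outer(cc$y, rep(1, ncols)) # y per cell
    shore_row <- outer(rep(1, nrows), shore(cc$x))
    dem_m <- pmax(0, (shore_row - ydist) * 0.005)
    dem_m <- dem_m + 0.2 * sin(ydist / 97) * cos(outer(rep(1, nrows), cc$x) / 131)
    dem_m[ydist > shore_row] <- 0
    dem <- mb_raster(dem_m, xmin = 0, ymax = H, pixel_size = ps, bands = "DEM")

    truth <- structure(list(
      config = config, template = template, coastline = coastline,
      coast_length = L, shore_jitter = year_jitter,
      mouths = if (n_mouth) mouths else data.frame(id = integer(0), x = numeric(0),
                                                   y = numeric(0), s = numeric(0),
                                                   forest_fraction = numeric(0)),
      catchments = catchments, deposits = deposits,
      deposit_polys = polys, deposit_years = years_list,
      logs = logs, road = road, buildings = buildings, dem = dem),
      class = "scene_truth")
    if (build_rasters) {
      truth$class_maps <- lapply(seq_len(config$n_years), function(y)
        build_class_map(truth, ps, y))
      truth$water_masks <- lapply(truth$class_maps, function(cm)
        raster_band(cm, 1) == CLASS_WATER)
    }
    truth
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %g x %g km, %d year(s), %d deposits (%d persistent), %d mouths\n",
              x$config$extent_m[1] / 1000, x$config$extent_m[2] / 1000,
              x$config$n_years, nrow(x$deposits), sum(x$deposits$persistent),
              nrow(x$mouths)))
  invisible(x)
}

#' Deposit ids present in a given year
#' @param truth a `scene_truth`.
#' @param year year index.
#' @export
deposits_in_year <- function(truth, year) {
  if (!nrow(truth$deposits)) return(integer(0))
  which(vapply(truth$deposit_years, function(y) year %in% y, TRUE))
}

#' Build the categorical land-cover map for one year at a given resolution
#'
#' Classes: 1 water, 2 sand, 3 vegetation, 4 driftwood, 5 infrastructure.
#' Deposits are burned from their pixel-exact truth polygons. Individual logs
#' are features below the satellite minimum mapping unit: they are burned
#' only in high-resolution (sub-metre to metre) maps, mirroring how a mapping
#' sensor cannot label features smaller than about a pixel, and they
#' additionally vanish naturally wherever they cover no pixel centre.
#'
#' @param truth a `scene_truth`.
#' @param pixel_size target pixel size in metres.
#' @param year year index (shoreline jitter and deposit presence are annual).
#' @param include_logs whether individual logs enter the map; defaults to
#'   `pixel_size <= 1`.
#' @return single-band integer `mb_raster`.
#' @export
build_class_map <- function(truth, pixel_size, year = 1L,
                            include_logs = pixel_size <= 1) {
  cfg <- truth$config
  W <- cfg$extent_m[1]; H <- cfg$extent_m[2]
  nrows <- round(H / pixel_size); ncols <- round(W / pixel_size)
  tpl <- mb_raster(matrix(0L, nrows, ncols), xmin = 0, ymax = H,
                   pixel_size = pixel_size, bands = "class")
  cc <- raster_coords(tpl)
  shore <- shore_y_fun(cfg)
  jit <- truth$shore_jitter[min(year, length(truth$shore_jitter))]
  shore_v <- shore(cc$x) + jit
  ymat <- matrix(cc$y, nrows, ncols)
  smat <- matrix(shore_v, nrows, ncols, byrow = TRUE)
  cm <- matrix(CLASS_VEG, nrows, ncols)
  band_w <- min(cfg$band_width_m, 0.5 * H)
  cm[ymat > smat - band_w] <- CLASS_SAND
  cm[ymat > smat] <- CLASS_WATER
  # river channels from each mouth to the bottom edge
  if (nrow(truth$mouths)) {
    halfw <- 12
    for (k in seq_len(nrow(truth$mouths))) {
      xm <- truth$mouths$x[k]
      colsel <- which(abs(cc$x - xm) <= halfw)
      if (length(colsel)) {
        rowsel <- which(cc$y <= shore_v[colsel[1]])
        cm[rowsel, colsel] <- CLASS_WATER
      }
    }
  }
  # infrastructure: road (buffered polyline) and buildings
  road <- truth$road
  rp <- project_to_polyline(as.vector(matrix(cc$x, nrows, ncols, byrow = TRUE)),
                            as.vector(ymat), road)
  cm[matrix(rp$dist, nrows, ncols) <= max(4, pixel_size)] <- CLASS_INFRA
  if (length(truth$buildings)) {
    bmask <- rasterize_polygons(lapply(truth$buildings, list), tpl, values = 1L)
    cm[bmask == 1L] <- CLASS_INFRA
  }
  # deposits present this year
  idx <- deposits_in_year(truth, year)
  for (i in idx) {
    burn <- rasterize_polygons(list(truth$deposit_polys[[i]]), tpl, values = 1L)
    cm[burn == 1L] <- CLASS_WOOD
  }
  # individual logs (static across years; below the satellite MMU)
  if (include_logs) for (lg in truth$logs) {
    burn <- rasterize_polygons(list(list(lg)), tpl, values = 1L)
    cm[burn == 1L & cm != CLASS_WATER] <- CLASS_WOOD
  }
  mb_raster(cm, xmin = 0, ymax = H, pixel_size = pixel_size, bands = "class")
}

render_class_spectra <- function(class_map, spectra, noise_sd, seed = NULL) {
  cm <- raster_band(class_map, 1)
  nb <- ncol(spectra)
  arr <- array(NA_real_, dim = c(nrow(cm), ncol(cm), nb))
  for (b in seq_len(nb)) {
    v <- matrix(spectra[cm, b], nrow(cm), ncol(cm))
    arr[, , b] <- v
  }
  if (noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, noise_sd)
  mb_raster(arr, xmin = class_map$xmin, ymax = class_map$ymax,
            pixel_size = class_map$pixel_size, bands = colnames(spectra))
}

#' Render the multi-scene satellite imagery of one year
#'
#' Each scene covers a vertical sub-extent (with ~10% overlap between
#' neighbouring scenes; their union covers the tile) and carries its own
#' multiplicative gain and additive offset per band -- the radiometric
#' discrepancies that histogram matching is meant to remove. Pixel values are
#' class spectra plus Gaussian noise. Deterministic for a fixed config seed.
#'
#' @param truth a `scene_truth`.
#' @param year year index in `1..n_years`.
#' @param config the [landscape_config()] (defaults to the truth's).
#' @return List of `mb_raster` scenes.
#' @export
render_scenes <- function(truth, year, config = truth$config) {
  if (year < 1L || year > config$n_years) stop_config("year %d outside 1..%d", year, config$n_years)
  with_seed(derive_seed(config$seed, paste0("render_scenes_", year)), {
    cm <- truth$class_maps[[year]]
    full <- render_class_spectra(cm, config$spectra, config$noise_sd)
    nsc <- config$n_scenes_per_year
    nc <- raster_ncol(full)
    if (nsc == 1L) {
      bounds <- cbind(1L, nc)
    } else {
      w <- ceiling(nc / nsc * 1.1)
      starts <- round(seq(1, nc - w + 1, length.out = nsc))
      bounds <- cbind(starts, pmin(starts + w - 1L, nc))
    }
    lapply(seq_len(nsc), function(k) {
      sc <- raster_crop(full, seq_len(raster_nrow(full)), bounds[k, 1]:bounds[k, 2])
      gain <- 1 + stats::rnorm(raster_nband(sc), 0, config$scene_gain_sd)
      off <- stats::rnorm(raster_nband(sc), 0, config$scene_offset_sd)
      for (b in seq_len(raster_nband(sc)))
        sc$values[, , b] <- sc$values[, , b] * gain[b] + off[b]
      sc
    })
  })
}

#' Render the coarse harmonisation reference composite
#'
#' A jitter-free, noise-free rendering at the reference pixel size (the
#' harmonised coarse-sensor composite that annual scenes are
#' histogram-matched against). Computed as the exact block mean of the
#' noiseless fine-resolution rendering of year 1.
#'
#' @param truth a `scene_truth`.
#' @param config the [landscape_config()].
#' @return `mb_raster` at `pixel_size_m$reference`.
#' @export
render_reference <- function(truth, config = truth$config) {
  fine <- render_class_spectra(truth$class_maps[[1]], config$spectra, 0)
  fac <- config$pixel_size_m$reference / fine$pixel_size
  if (abs(fac - round(fac)) > 1e-8)
    stop_config("reference pixel size must be a multiple of the truth pixel size")
  block_mean(fine, round(fac))
}

#' Render high-resolution aerial imagery of the same truth
#'
#' A 4-band render at the aerial pixel size, resolving deposits below the
#' satellite minimum mapping unit (individual logs). No scene jitter.
#'
#' @param truth a `scene_truth`.
#' @param year year index.
#' @param config the [landscape_config()].
#' @return `mb_raster` at `pixel_size_m$aerial`.
#' @export
render_aerial <- function(truth, year = 1L, config = truth$config) {
  stopifnot(config$pixel_size_m$aerial < config$pixel_size_m$satellite)
  with_seed(derive_seed(config$seed, paste0("render_aerial_", year)), {
    cm <- build_class_map(truth, config$pixel_size_m$aerial, year)
    render_class_spectra(cm, config$spectra, config$aerial_noise_sd)
  })
}

#' Write the ground truth of a landscape to disk
#'
#' Rasters as ESRI ASCII grids, vector layers as GeoJSON, and a YAML manifest
#' recording the configuration and seed.
#'
#' @param truth a `scene_truth`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(truth$dem, file.path(dir, "dem"))
  for (y in seq_along(truth$class_maps))
    write_raster(truth$class_maps[[y]], file.path(dir, sprintf("class_year%d", y)))
  if (nrow(truth$deposits)) {
    props <- truth$deposits
    props$years <- vapply(truth$deposit_years, paste, "", collapse = ",")
    write_geojson(truth$deposit_polys, props, file.path(dir, "deposits.geojson"))
  }
  if (nrow(truth$mouths))
    write_geojson(lapply(seq_len(nrow(truth$mouths)),
                         function(i) c(truth$mouths$x[i], truth$mouths$y[i])),
                  truth$mouths, file.path(dir, "river_mouths.geojson"))
  if (!is.null(truth$catchments)) {
    H <- truth$config$extent_m[2]
    geoms <- lapply(seq_len(nrow(truth$catchments)), function(i) {
      with(truth$catchments[i, ], list(cbind(c(x_min, x_max, x_max, x_min),
                                             c(0, 0, H, H))))
    })
    write_geojson(geoms, truth$catchments, file.path(dir, "catchments.geojson"))
  }
  write_geojson(c(list(truth$road), lapply(truth$buildings, list)),
                data.frame(kind = c("road", rep("building", length(truth$buildings)))),
                file.path(dir, "infrastructure.geojson"))
  yaml::write_yaml(list(seed = truth$config$seed,
                        extent_m = truth$config$extent_m,
                        n_years = truth$config$n_years,
                        n_deposits = nrow(truth$deposits)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}
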