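test_that("generator is deterministic and honours the empty-densities case", {
  cfg0 <- landscape_config(extent_m = c(900, 600),
                           pixel_size_m = list(satellite = 3, aerial = 1, reference = 30),
                           cluster_density_per_km2 = 0, background_density_per_km2 = 0,
                           aerial_log_density_per_km2 = 0, seed = 3)
  tr0 <- generate_landscape(cfg0)
  expect_equal(nrow(tr0$deposits), 0L)
  expect_equal(length(tr0$class_maps), 3L)       # other layers still populated
  expect_gt(sum(raster_band(tr0$class_maps[[1]], 1) == 1), 0)  # water present

  tr1 <- small_truth(seed = 7)
  tr2 <- small_truth(seed = 7)
  expect_identical(tr1$deposits, tr2$deposits)
  expect_identical(tr1$deposit_polys, tr2$deposit_polys)
  expect_identical(tr1$class_maps[[2]]$values, tr2$class_maps[[2]]$values)
})

test_that("generator rejects invalid configurations", {
  expect_error(landscape_config(extent_m = c(0, 100)), "extent")
  expect_error(landscape_config(decay_scale_km = -1), "decay")
  expect_error(landscape_config(river_mouths = data.frame(x = numeric(0),
                                                          forest_fraction = numeric(0))),
               "river_mouths")
})

test_that("deposit polygon areas equal their rasterized pixel areas exactly", {
  tr <- small_truth(seed = 5)
  expect_gt(nrow(tr$deposits), 5)
  shoelace <- vapply(seq_len(nrow(tr$deposits)),
                     function(i) polygon_area(tr$deposit_polys[[i]]), 0)
  expect_close(shoelace, tr$deposits$area_m2, tol = 1e-6)
  # class-map driftwood area equals the union of per-year deposit pixels
  for (y in 1:3) {
    idx <- deposits_in_year(tr, y)
    px <- unique(unlist(lapply(tr$deposit_polys[idx], attr, "cells")))
    expect_equal(sum(raster_band(tr$class_maps[[y]], 1) == 4), length(px))
  }
})

test_that("alongshore placement follows the exponential distance decay", {
  cfg <- landscape_config(
    extent_m = c(1.2e6, 4200),
    pixel_size_m = list(satellite = 3, aerial = 1, reference = 30, truth = 200),
    river_mouths = data.frame(x = 6e5, forest_fraction = 0.9),
    decay_scale_km = 112,
    cluster_density_per_km2 = 40, background_density_per_km2 = 12,
    aerial_log_density_per_km2 = 0, shore_amp_m = 0, seed = 21)
  tr <- generate_landscape(cfg, build_rasters = FALSE)
  expect_gt(nrow(tr$deposits), 3000)
  dd <- distance_decay(tr$deposits, tr$mouths)
  expected <- 1 - exp(-200 / 112)
  expect_lt(abs(dd$fraction_within(200) - expected), 0.03)
})

test_that("cluster-setting deposits are larger on average than background ones", {
  cfg <- landscape_config(
    extent_m = c(399000, 4200),
    pixel_size_m = list(satellite = 3, aerial = 1, reference = 30, truth = 100),
    river_mouths = data.frame(x = c(1e5, 3e5), forest_fraction = c(0.9, 0.6)),
    cluster_density_per_km2 = 8, background_density_per_km2 = 8,
    aerial_log_density_per_km2 = 0, shore_amp_m = 0, seed = 9)
  tr <- generate_landscape(cfg, build_rasters = FALSE)
  tb <- tr$deposits
  expect_gt(sum(tb$setting == "coastal_cluster"), 30)
  expect_gt(mean(tb$size_m2[tb$setting == "coastal_cluster"]),
            mean(tb$size_m2[tb$setting == "background"]))
})

test_that("persistence fraction converges to 1 - remobilization_prob", {
  cfg <- landscape_config(
    extent_m = c(399000, 4200),
    pixel_size_m = list(satellite = 3, aerial = 1, reference = 30, truth = 100),
    river_mouths = data.frame(x = 2e5, forest_fraction = 0.9),
    cluster_density_per_km2 = 10, background_density_per_km2 = 10,
    remobilization_prob = 0.79,
    aerial_log_density_per_km2 = 0, shore_amp_m = 0, seed = 13)
  tr <- generate_landscape(cfg, build_rasters = FALSE)
  n <- nrow(tr$deposits)
  expect_gt(n, 300)
  p_hat <- mean(tr$deposits$persistent)
  se <- sqrt(0.21 * 0.79 / n)
  expect_lt(abs(p_hat - 0.21), 4 * se)
  # non-persistent deposits appear in >= 1 but not all years
  yrs <- lengths(tr$deposit_years)
  expect_true(all(yrs[tr$deposits$persistent] == 3))
  expect_true(all(yrs[!tr$deposits$persistent] >= 1 &
                    yrs[!tr$deposits$persistent] < 3))
})

test_that("noiseless scenes render exact class spectra; jitter moves histograms", {
  tr <- small_truth(seed = 7)
  cfg <- tr$config
  cfg$noise_sd <- 0; cfg$scene_gain_sd <- 0; cfg$scene_offset_sd <- 0
  cfg$n_scenes_per_year <- 1L
  sc <- render_scenes(tr, 1, cfg)
  cm <- raster_band(tr$class_maps[[1]], 1)
  for (b in 1:4) {
    for (cl in 1:5) {
      sel <- which(cm == cl)
      if (!length(sel)) next
      expect_close(sc[[1]]$values[, , b][sel], cfg$spectra[cl, b], tol = 1e-12)
    }
  }
  # gains differ between scenes -> per-band distributions differ
  cfg2 <- tr$config; cfg2$noise_sd <- 0; cfg2$scene_gain_sd <- 0.2
  sc2 <- render_scenes(tr, 1, cfg2)
  ov <- intersect(seq_len(raster_ncol(sc2[[1]])) + 0,
                  seq_len(raster_ncol(sc2[[2]])) + round((sc2[[2]]$xmin - sc2[[1]]$xmin) / 3))
  ks <- suppressWarnings(stats::ks.test(as.vector(sc2[[1]]$values[, , 1]),
                                        as.vector(sc2[[2]]$values[, , 1])))
  expect_gt(ks$statistic, 0)
})

test_that("single scene per year covers the full extent", {
  tr <- small_truth(seed = 7)
  cfg <- tr$config; cfg$n_scenes_per_year <- 1L
  sc <- render_scenes(tr, 1, cfg)
  expect_length(sc, 1L)
  expect_equal(unname(raster_extent(sc[[1]])), c(0, 1560, 0, 780))
})

test_that("reference render is the block mean of the noiseless fine render", {
  tr <- small_truth(seed = 7)
  ref <- render_reference(tr)
  expect_equal(dim(ref$values)[1:2], c(26L, 52L))
  cfg <- tr$config; cfg$noise_sd <- 0
  cfg$n_scenes_per_year <- 1L; cfg$scene_gain_sd <- 0; cfg$scene_offset_sd <- 0
  fine <- render_scenes(tr, 1, cfg)[[1]]
  # independent block averaging oracle
  fac <- 10
  for (b in c(1, 4)) {
    m <- fine$values[, , b]
    ri <- ceiling(seq_len(nrow(m)) / fac); ci <- ceiling(seq_len(ncol(m)) / fac)
    oracle <- t(rowsum(t(rowsum(m, ri)), ci)) / fac^2
    expect_close(ref$values[, , b], oracle, tol = 1e-9)
  }
})

test_that("aerial render agrees with the satellite render after block-averaging", {
  tr <- small_truth(seed = 7, aerial_log_density_per_km2 = 0)
  cfg <- tr$config
  cfg$noise_sd <- 0; cfg$aerial_noise_sd <- 0
  cfg$scene_gain_sd <- 0; cfg$scene_offset_sd <- 0
  aer <- render_aerial(tr, 1, cfg)
  cfg$n_scenes_per_year <- 1L
  sat <- render_scenes(tr, 1, cfg)[[1]]
  agg <- block_mean(aer, 3)
  # class maps can differ at mixed pixels; compare where the 3 m pixel is pure
  cm_a <- raster_band(build_class_map(tr, 1, 1), 1)
  pure <- block_mean(rast(cm_a * 1, ps = 1), 3)$values[, , 1]
  pure_px <- pure == round(pure) & matrix(TRUE, nrow(pure), ncol(pure))
  same <- abs(agg$values[, , 4] - sat$values[, , 4]) < 1e-9
  expect_gt(mean(same[pure_px]), 0.999)
  # determinism
  aer2 <- render_aerial(tr, 1, cfg)
  expect_identical(aer$values, aer2$values)
})

test_that("individual logs resolve at aerial resolution, not at 3 m", {
  tr <- small_truth(seed = 7)
  cm_a <- raster_band(build_class_map(tr, 1, 1), 1)
  cm_s <- raster_band(tr$class_maps[[1]], 1)
  dep_px_aerial <- sum(cm_a == 4)
  dep_area_sat <- sum(cm_s == 4) * 9
  # union of deposit pixels (deposits may overlap on a crowded coast)
  idx <- deposits_in_year(tr, 1)
  dep_union <- length(unique(unlist(lapply(tr$deposit_polys[idx], attr, "cells")))) * 9
  expect_gt(dep_px_aerial, dep_union)        # logs add area at 1 m
  expect_equal(dep_area_sat, dep_union)      # but none at 3 m
})
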