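# Shared fixtures, built in code at test time.

# tiny raster from a matrix (3 m pixels by default)
rast <- function(m, ps = 3, xmin = 0, bands = NULL) {
  mb_raster(m, xmin = xmin, pixel_size = ps, bands = bands)
}

# one-pixel-per-value multiband raster stack for medoid tests
spectral_stack <- function(vectors, ps = 1) {
  lapply(vectors, function(v)
    mb_raster(array(v, dim = c(1, 1, length(v))), pixel_size = ps))
}

# a small high-SNR landscape shared by several generator-facing tests
small_truth <- function(seed = 7, ...) {
  defaults <- list(
    extent_m = c(1560, 780),
    pixel_size_m = list(satellite = 3, aerial = 1, reference = 30),
    river_mouths = data.frame(x = c(400, 1100), forest_fraction = c(0.9, 0.4)),
    cluster_density_per_km2 = 40, background_density_per_km2 = 8,
    cluster_radius_km = 1, delta_radius_km = 0.2,
    aerial_log_density_per_km2 = 80,
    shore_wavelength_m = 800, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  generate_landscape(do.call(landscape_config, args))
}

# mask matrix helpers
ring_mask <- function(outer = 5, hole = 3, pad = 1) {
  n <- outer + 2 * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(outer), pad + seq_len(outer)] <- TRUE
  h0 <- pad + (outer - hole) %/% 2
  m[h0 + seq_len(hole), h0 + seq_len(hole)] <- FALSE
  m
}

expect_close <- function(x, y, tol = 1e-8) expect_lt(max(abs(x - y)), tol)
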