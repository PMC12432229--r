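# Radiometric harmonisation and annual compositing: per-pixel medoid
# selection, empirical-quantile histogram matching against a coarse reference
# composite, seam-free merging of overlapping scenes, and stacking of an
# elevation band.

#' Pixel-wise medoid composite of co-registered rasters
#'
#' For every pixel, the output spectral vector is the actual observation
#' minimising the sum of pairwise distances to all other valid observations at
#' that pixel -- a robust composite that never invents spectra. Pixels with no
#' valid observation are nodata.
#'
#' @param stack list of `mb_raster`s on an identical grid.
#' @param metric distance between spectral vectors: `"euclidean"` (default) or
#'   `"manhattan"`.
#' @return An `mb_raster` on the shared grid.
#' @export
medoid_composite <- function(stack, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (length(stack) == 0L) stop_config("medoid_composite: empty stack")
  for (s in stack[-1]) if (!same_grid(stack[[1]], s))
    stop_config("medoid_composite: rasters are not on the same grid")
  if (length(stack) == 1L) return(stack[[1]])
  k <- length(stack)
  nb <- raster_nband(stack[[1]])
  npx <- raster_nrow(stack[[1]]) * raster_ncol(stack[[1]])
  obs <- array(NA_real_, dim = c(npx, nb, k))
  for (j in seq_len(k)) obs[, , j] <- matrix(stack[[j]]$values, npx, nb)
  valid <- !apply(is.na(obs), c(1, 3), any)      # npx x k
  # summed distance of observation j to all others, per pixel
  dsum <- matrix(0, npx, k)
  for (j in seq_len(k - 1)) for (l in (j + 1):k) {
    d <- if (metric == "euclidean")
      sqrt(rowSums((obs[, , j, drop = FALSE] - obs[, , l, drop = FALSE])^2))
    else rowSums(abs(obs[, , j, drop = FALSE] - obs[, , l, drop = FALSE]))
    d[!valid[, j] | !valid[, l]] <- 0            # invalid pairs contribute nothing
    dsum[, j] <- dsum[, j] + d
    dsum[, l] <- dsum[, l] + d
  }
  dsum[!valid] <- Inf
  pick <- max.col(-dsum, ties.method = "first")
  any_valid <- rowSums(valid) > 0
  out <- matrix(NA_real_, npx, nb)
  sel <- cbind(rep(seq_len(npx), nb), rep(seq_len(nb), each = npx),
               rep(pick, nb))
  out[any_valid, ] <- matrix(obs[sel], npx, nb)[any_valid, ]
  tpl <- stack[[1]]
  mb_raster(array(out, dim = c(raster_nrow(tpl), raster_ncol(tpl), nb)),
            xmin = tpl$xmin, ymax = tpl$ymax, pixel_size = tpl$pixel_size,
            bands = tpl$bands, crs = tpl$crs)
}

#' Histogram matching by monotone empirical-quantile mapping
#'
#' Per band, source values are mapped so that their empirical CDF matches the
#' reference's, using linear interpolation between empirical quantiles. The
#' reference may be on a different (e.g. coarser) grid; only its value
#' distribution is used. Valid-pixel masks are preserved.
#'
#' @param source,reference `mb_raster`s with the same band count.
#' @param n_quantiles number of quantile knots (255 suffices for smooth maps).
#' @return The matched `mb_raster` on the source grid.
#' @export
histogram_match <- function(source, reference, n_quantiles = 255L) {
  if (raster_nband(source) != raster_nband(reference))
    stop_config("histogram_match: band count mismatch")
  out <- source
  probs <- seq(0, 1, length.out = n_quantiles)
  for (b in seq_len(raster_nband(source))) {
    sv <- source$values[, , b]
    rv <- reference$values[, , b]
    ok <- !is.na(sv)
    if (!any(ok) || !any(!is.na(rv)))
      stop_config("histogram_match: no valid pixels to match (band %d)", b)
    qs <- stats::quantile(sv[ok], probs, names = FALSE, type = 7)
    qr <- stats::quantile(rv, probs, names = FALSE, type = 7, na.rm = TRUE)
    # enforce strict monotonicity of knots for approx()
    eps <- 1e-12 * max(1, abs(qs[n_quantiles] - qs[1]))
    qs <- qs + seq_len(n_quantiles) * eps
    mapped <- stats::approx(qs, qr, xout = sv[ok], rule = 2)$y
    m <- sv; m[ok] <- mapped
    out$values[, , b] <- m
  }
  out
}

#' Merge scenes onto the full tile grid
#'
#' @param scenes list of `mb_raster`s sharing pixel size and alignment.
#' @param overlap_rule how overlapping pixels are resolved: per-pixel medoid
#'   across contributing scenes (with a single contributor, that value).
#' @return An `mb_raster` covering the union extent.
#' @noRd
merge_scenes <- function(scenes) {
  ps <- scenes[[1]]$pixel_size
  exts <- vapply(scenes, raster_extent, numeric(4))
  xmin <- min(exts["xmin", ]); xmax <- max(exts["xmax", ])
  ymin <- min(exts["ymin", ]); ymax <- max(exts["ymax", ])
  nc <- round((xmax - xmin) / ps); nr <- round((ymax - ymin) / ps)
  nb <- raster_nband(scenes[[1]])
  placed <- lapply(scenes, function(s) {
    full <- array(NA_real_, dim = c(nr, nc, nb))
    r0 <- round((ymax - s$ymax) / ps); c0 <- round((s$xmin - xmin) / ps)
    full[r0 + seq_len(raster_nrow(s)), c0 + seq_len(raster_ncol(s)), ] <- s$values
    mb_raster(full, xmin = xmin, ymax = ymax, pixel_size = ps,
              bands = s$bands, crs = s$crs)
  })
  medoid_composite(placed)
}

#' Build a harmonised annual composite
#'
#' Every scene is histogram-matched to the reference composite, then merged
#' onto the tile grid; overlaps are resolved by the per-pixel medoid of the
#' contributing scenes.
#'
#' @param scenes list of `mb_raster` scenes of one year.
#' @param reference the coarse reference composite (see [render_reference()]).
#' @return An `mb_raster` covering the union of scene extents.
#' @export
build_annual_composite <- function(scenes, reference) {
  if (length(scenes) == 0L) stop_config("build_annual_composite: no scenes")
  matched <- lapply(scenes, histogram_match, reference = reference)
  if (length(matched) == 1L) return(matched[[1]])
  merge_scenes(matched)
}

#' Stack an elevation band onto a composite
#'
#' The DEM is bicubically resampled to the composite grid and appended as an
#' additional band labelled `"DEM"`.
#'
#' @param composite an `mb_raster` (typically 4 bands).
#' @param dem a single-band `mb_raster` of elevations covering the same extent.
#' @return An `mb_raster` with one extra band.
#' @export
stack_elevation <- function(composite, dem) {
  dem_r <- if (same_grid(composite, dem)) dem else {
    r <- raster_resample(dem, composite$pixel_size)
    if (!isTRUE(all(dim(r$values)[1:2] == dim(composite$values)[1:2])) ||
        abs(r$xmin - composite$xmin) > 1e-6 || abs(r$ymax - composite$ymax) > 1e-6)
      stop_config("stack_elevation: DEM cannot be co-registered to the composite grid")
    r
  }
  arr <- array(NA_real_, dim = c(raster_nrow(composite), raster_ncol(composite),
                                 raster_nband(composite) + 1L))
  arr[, , seq_len(raster_nband(composite))] <- composite$values
  arr[, , raster_nband(composite) + 1L] <- dem_r$values[, , 1]
  mb_raster(arr, xmin = composite$xmin, ymax = composite$ymax,
            pixel_size = composite$pixel_size,
            bands = c(composite$bands, "DEM"), crs = composite$crs)
}
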