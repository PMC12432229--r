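# Multi-year fusion of binary driftwood predictions into stable deposits:
# per-pixel presence probability across years, dual-threshold extraction
# (presence seeds, shape grows), water persistence masking, and the
# water-fraction / infrastructure / interior-hole filters.

#' Per-pixel probability of driftwood presence across years
#'
#' The fraction of years with a detection among years with a valid
#' observation at that pixel; pixels never observed are nodata.
#'
#' @param annual_masks list (>= 2) of 0/1 matrices or single-band
#'   `mb_raster`s on a common grid; `NA` marks no valid observation.
#' @return A single-band `mb_raster` (or matrix, if matrices were supplied)
#'   of probabilities.
#' @export
presence_probability <- function(annual_masks) {
  if (length(annual_masks) < 2L)
    stop_config("presence_probability: need >= 2 annual masks")
  tpl <- annual_masks[[1]]
  mats <- lapply(annual_masks, function(m) if (inherits(m, "mb_raster")) raster_band(m, 1) else m)
  d <- dim(mats[[1]])
  for (m in mats) if (!isTRUE(all(dim(m) == d)))
    stop_config("presence_probability: masks are not co-registered")
  det <- Reduce(`+`, lapply(mats, function(m) { m[is.na(m)] <- 0; m }))
  obs <- Reduce(`+`, lapply(mats, function(m) (!is.na(m)) * 1))
  p <- det / obs
  p[obs == 0] <- NA_real_
  if (inherits(tpl, "mb_raster"))
    mb_raster(p, xmin = tpl$xmin, ymax = tpl$ymax, pixel_size = tpl$pixel_size,
              bands = "presence")
  else p
}

#' A set of vectorized driftwood deposits
#'
#' Internal constructor: carries the georeference, per-deposit pixel sets,
#' polygons (pixel-exact rings) and an attribute table.
#' @noRd
new_deposit_set <- function(table, polys, cells, template) {
  structure(list(table = table, polys = polys, cells = cells,
                 template = template), class = "deposit_set")
}

#' @export
print.deposit_set <- function(x, ...) {
  cat(sprintf("<deposit_set> %d deposits, total %.0f m2 (pixel %g m)\n",
              nrow(x$table), sum(x$table$area_m2), x$template$pixel_size))
  invisible(x)
}

#' Number of deposits in a deposit set
#' @param x a `deposit_set`.
#' @export
n_deposits <- function(x) nrow(x$table)

#' Extract stable deposits from a presence-probability raster
#'
#' Connected components (8-connected by default) of pixels with probability
#' at or above the shape threshold become deposits if and only if they
#' contain at least one seed pixel at or above the presence threshold; the
#' lower shape threshold delineates the final outline. Polygons preserve
#' interior rings; areas are planar (pixel count x pixel area).
#'
#' @param prob probability `mb_raster` (or matrix with `template`).
#' @param t_presence seed threshold (default 0.6).
#' @param t_shape outline threshold (default 0.5, must be <= `t_presence`).
#' @param connectivity 8 (default) or 4.
#' @param template georeference when `prob` is a bare matrix.
#' @return A `deposit_set` with columns `id`, `area_m2`, `n_pixels`,
#'   `hole_count`, `x`, `y` (centroid).
#' @export
extract_deposits <- function(prob, t_presence = 0.6, t_shape = 0.5,
                             connectivity = 8, template = NULL) {
  if (inherits(prob, "mb_raster")) { template <- prob; pm <- raster_band(prob, 1) }
  else pm <- prob
  if (is.null(template)) stop_config("extract_deposits: georeference required")
  if (t_presence <= 0 || t_presence > 1 || t_shape <= 0 || t_shape > 1 ||
      t_shape > t_presence)
    stop_config("invalid thresholds: need 0 < t_shape <= t_presence <= 1")
  shape <- !is.na(pm) & pm >= t_shape
  lab <- label_components(shape, connectivity)
  if (max(lab) == 0L)
    return(new_deposit_set(empty_deposit_table(), list(), list(), template))
  seed_lab <- unique(lab[!is.na(pm) & pm >= t_presence & lab > 0L])
  keep <- sort(seed_lab[seed_lab > 0L])
  if (!length(keep))
    return(new_deposit_set(empty_deposit_table(), list(), list(), template))
  ps <- template$pixel_size
  cc <- raster_coords(template)
  polys <- vector("list", length(keep)); cells <- vector("list", length(keep))
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    cells[[i]] <- which(lab == keep[i])
    mask <- lab == keep[i]
    polys[[i]] <- component_polygon(mask, template)
    rc <- arrayInd(cells[[i]], dim(pm))
    rows[[i]] <- data.frame(id = i, n_pixels = length(cells[[i]]),
                            area_m2 = length(cells[[i]]) * ps^2,
                            hole_count = count_holes(mask),
                            x = mean(cc$x[rc[, 2]]), y = mean(cc$y[rc[, 1]]))
  }
  new_deposit_set(do.call(rbind, rows), polys, cells, template)
}

empty_deposit_table <- function() {
  data.frame(id = integer(0), n_pixels = integer(0), area_m2 = numeric(0),
             hole_count = integer(0), x = numeric(0), y = numeric(0))
}

#' Vectorize a binary raster into measured polygons
#'
#' Every 8-connected region becomes a polygon whose planar area equals pixel
#' count times pixel area, with interior rings counted exactly.
#'
#' @param mask binary matrix or single-band `mb_raster`.
#' @param template georeference when `mask` is a bare matrix.
#' @return A `deposit_set`.
#' @export
vectorize_and_measure <- function(mask, template = NULL) {
  if (inherits(mask, "mb_raster")) { template <- mask; mask <- raster_band(mask, 1) }
  if (is.null(template)) stop_config("vectorize_and_measure: georeference required")
  pm <- (mask > 0) * 1
  pm[is.na(mask)] <- NA
  extract_deposits(pm, t_presence = 1, t_shape = 1, template = template)
}

#' Build a persistent-water mask from annual water flags
#'
#' A pixel is water iff it was flagged water in strictly more than
#' `persistence` of the observations.
#'
#' @param water_flags list of 0/1 matrices or `mb_raster`s (`NA` = not
#'   observed).
#' @param persistence fraction threshold (default 0.2).
#' @return Logical matrix (or `mb_raster` if the input was one).
#' @export
build_water_mask <- function(water_flags, persistence = 0.2) {
  if (!length(water_flags)) stop_config("build_water_mask: empty list")
  tpl <- water_flags[[1]]
  mats <- lapply(water_flags, function(m) if (inherits(m, "mb_raster")) raster_band(m, 1) else m)
  det <- Reduce(`+`, lapply(mats, function(m) { m[is.na(m)] <- 0; m * 1 }))
  obs <- Reduce(`+`, lapply(mats, function(m) (!is.na(m)) * 1))
  w <- det / pmax(obs, 1) > persistence
  w[obs == 0] <- FALSE
  if (inherits(tpl, "mb_raster"))
    mb_raster(w * 1, xmin = tpl$xmin, ymax = tpl$ymax,
              pixel_size = tpl$pixel_size, bands = "water")
  else w
}

#' Filter deposits by water coverage, infrastructure and interior holes
#'
#' A deposit survives iff its water fraction is <= `max_water_fraction`, it
#' intersects no infrastructure feature, and it has at most `max_holes`
#' interior rings (a deposit with exactly `max_holes` holes is kept). The
#' removal log records the first failed rule per removed deposit.
#'
#' @param deposits a `deposit_set`.
#' @param water_mask logical matrix or `mb_raster` on the deposit grid.
#' @param infrastructure either a logical matrix/`mb_raster` of rasterized
#'   infrastructure, or a list of vector features (ring matrices / polylines
#'   tagged `LineString`) rasterized internally.
#' @param max_water_fraction strictly-greater removal threshold (default 0.2).
#' @param max_holes maximum interior rings (default 5; "more than 5" removed).
#' @return list with `deposits` (surviving `deposit_set`, water fractions
#'   attached) and `removed` (data.frame `id`, `rule`).
#' @export
filter_deposits <- function(deposits, water_mask = NULL, infrastructure = NULL,
                            max_water_fraction = 0.2, max_holes = 5L) {
  tb <- deposits$table
  if (!nrow(tb))
    return(list(deposits = deposits, removed = data.frame(id = integer(0), rule = character(0))))
  wm <- if (inherits(water_mask, "mb_raster")) raster_band(water_mask, 1) > 0 else water_mask
  im <- infrastructure
  if (!is.null(im) && !is.matrix(im) && !inherits(im, "mb_raster")) {
    tpl <- deposits$template
    rr <- matrix(FALSE, raster_nrow(tpl), raster_ncol(tpl))
    for (f in im) {
      if (identical(attr(f, "type"), "LineString")) {
        cc <- raster_coords(tpl)
        pj <- project_to_polyline(rep(cc$x, each = length(cc$y)),
                                  rep(cc$y, times = length(cc$x)), f)
        rr <- rr | matrix(pj$dist <= tpl$pixel_size, length(cc$y), length(cc$x))
      } else {
        rings <- if (is.matrix(f)) list(f) else f
        rr <- rr | rasterize_polygons(list(rings), tpl, values = 1L) == 1L
      }
    }
    im <- rr
  } else if (inherits(im, "mb_raster")) im <- raster_band(im, 1) > 0
  wf <- vapply(deposits$cells, function(cl)
    if (is.null(wm)) 0 else mean(wm[cl], na.rm = TRUE), 0)
  hits_infra <- vapply(deposits$cells, function(cl)
    !is.null(im) && any(im[cl], na.rm = TRUE), TRUE)
  tb$water_fraction <- wf
  rule <- rep(NA_character_, nrow(tb))
  rule[wf > max_water_fraction] <- "water"
  rule[is.na(rule) & hits_infra] <- "infrastructure"
  rule[is.na(rule) & tb$hole_count > max_holes] <- "holes"
  keep <- is.na(rule)
  kept <- new_deposit_set(transform(tb[keep, , drop = FALSE], id = seq_len(sum(keep))),
                          deposits$polys[keep], deposits$cells[keep],
                          deposits$template)
  rownames(kept$table) <- NULL
  list(deposits = kept,
       removed = data.frame(id = tb$id[!keep], rule = rule[!keep]))
}

#' Write a deposit set to GeoJSON
#' @param deposits a `deposit_set`.
#' @param path output file.
#' @export
write_deposits <- function(deposits, path) {
  if (!nrow(deposits$table)) {
    jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                         path, auto_unbox = TRUE)
    return(invisible(path))
  }
  write_geojson(deposits$polys, deposits$table, path)
}
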