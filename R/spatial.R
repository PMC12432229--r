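# Hexagonal-grid aggregation and the coastal source analyses: catchment
# assignment along the coastline and distance decay of deposit cover from
# river mouths.

#' Build a regular hexagonal grid covering an extent
#'
#' Pointy-top hexagons with incircle diameter equal to `cell_size_m` (the
#' "10 x 10 km" cell convention: opposite edges 10 km apart). Interior cells
#' have exactly 6 edge-sharing neighbours; on a hexagonal tessellation
#' queen- and rook-contiguity coincide.
#'
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` (metres) or an
#'   `mb_raster`.
#' @param cell_size_m incircle diameter in metres (default 10000).
#' @return An object of class `hex_grid`: data.frame `cells` (id, axial q/r,
#'   centre), list `polys` of hexagon rings, list `nb` of neighbour indices.
#' @export
make_hex_grid <- function(extent, cell_size_m = 10000) {
  if (inherits(extent, "mb_raster")) {
    e <- raster_extent(extent)
    extent <- c(e["xmin"], e["xmax"], e["ymin"], e["ymax"])
  }
  stopifnot(cell_size_m > 0, extent[2] > extent[1], extent[4] > extent[3])
  s <- cell_size_m
  R <- s / sqrt(3)                       # circumradius
  r_lo <- floor((extent[3] - R) / (1.5 * R)); r_hi <- ceiling((extent[4] + R) / (1.5 * R))
  rows <- list(); k <- 0L
  for (r in r_lo:r_hi) {
    cy <- 1.5 * R * r
    q_lo <- floor((extent[1] - s) / s - r / 2); q_hi <- ceiling((extent[2] + s) / s - r / 2)
    for (q in q_lo:q_hi) {
      cx <- s * (q + r / 2)
      # keep cells whose hexagon can intersect the extent
      if (cx < extent[1] - s || cx > extent[2] + s ||
          cy < extent[3] - s || cy > extent[4] + s) next
      k <- k + 1L
      rows[[k]] <- data.frame(id = k, q = q, r = r, cx = cx, cy = cy)
    }
  }
  cells <- do.call(rbind, rows)
  ang <- (pi / 180) * (30 + 60 * 0:5) + pi / 3  # pointy-top vertex angles
  polys <- lapply(seq_len(nrow(cells)), function(i)
    cbind(cells$cx[i] + R * cos(ang), cells$cy[i] + R * sin(ang)))
  key <- paste(cells$q, cells$r)
  dirs <- rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))
  nb <- lapply(seq_len(nrow(cells)), function(i) {
    nk <- paste(cells$q[i] + dirs[, 1], cells$r[i] + dirs[, 2])
    sort(stats::na.omit(match(nk, key)))
  })
  structure(list(cells = cells, polys = polys, nb = nb, cell_size = s, R = R),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d cells, incircle diameter %g km\n",
              nrow(x$cells), x$cell_size / 1000))
  invisible(x)
}

#' Subset a hexagonal grid to selected cells
#'
#' Keeps the chosen cells and re-indexes the neighbour lists (useful to
#' restrict spatial statistics to the coastal strip where deposits can occur,
#' so empty open-water or inland cells do not dilute the field).
#'
#' @param grid a `hex_grid`.
#' @param keep logical vector or integer cell ids.
#' @return A `hex_grid` over the kept cells (any `stats` rows subset too).
#' @export
grid_subset <- function(grid, keep) {
  if (is.logical(keep)) keep <- which(keep)
  keep <- sort(unique(keep))
  remap <- match(seq_len(nrow(grid$cells)), keep)
  out <- grid
  out$cells <- grid$cells[keep, , drop = FALSE]
  out$cells$id <- seq_along(keep)
  out$polys <- grid$polys[keep]
  out$nb <- lapply(grid$nb[keep], function(nn) sort(stats::na.omit(remap[nn])))
  if (!is.null(grid$stats)) {
    out$stats <- grid$stats[keep, , drop = FALSE]
    out$stats$id <- seq_along(keep)
  }
  attr(out, "kept") <- keep
  out
}

#' Locate points in hexagonal cells
#' @param grid a `hex_grid`.
#' @param px,py point coordinates (metres).
#' @return Integer cell ids (`NA` outside the grid).
#' @export
hex_locate <- function(grid, px, py) {
  s <- grid$cell_size; R <- grid$R
  rf <- py / (1.5 * R)
  qf <- px / s - rf / 2
  # cube rounding
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fx <- dx > dy & dx > dz
  fz <- !fx & dz > dy
  rx[fx] <- -ry[fx] - rz[fx]
  rz[fz] <- -rx[fz] - ry[fz]
  match(paste(rx, rz), paste(grid$cells$q, grid$cells$r))
}

#' Aggregate deposits onto a hexagonal grid
#'
#' Deposit area is split among cells by geometric intersection (at pixel
#' fidelity for raster-backed deposit sets; by centroid for point-like
#' records); counts are assigned to the centroid's cell. Densities are counts
#' per km2 of cell land area.
#'
#' @param deposits a `deposit_set`, or a data.frame with `x`, `y`,
#'   `area_m2`.
#' @param grid a [make_hex_grid()] grid.
#' @param land_mask optional logical matrix / `mb_raster` (TRUE = land) on
#'   the deposit grid, used for per-cell land area; defaults to the full
#'   hexagon area.
#' @return The grid with a `stats` data.frame: per-cell `wood_area_m2`,
#'   `deposit_count`, `land_area_km2`, `cover_fraction`, `density_per_km2`.
#' @export
aggregate_to_grid <- function(deposits, grid, land_mask = NULL) {
  n <- nrow(grid$cells)
  area <- numeric(n); cnt <- integer(n)
  hex_area_km2 <- (sqrt(3) / 2) * (grid$cell_size / 1000)^2
  land <- rep(hex_area_km2, n)
  if (inherits(deposits, "deposit_set")) {
    tpl <- deposits$template
    cc <- raster_coords(tpl)
    ps2 <- tpl$pixel_size^2
    for (i in seq_len(nrow(deposits$table))) {
      rc <- arrayInd(deposits$cells[[i]], c(raster_nrow(tpl), raster_ncol(tpl)))
      ids <- hex_locate(grid, cc$x[rc[, 2]], cc$y[rc[, 1]])
      tab <- table(ids[!is.na(ids)])
      area[as.integer(names(tab))] <- area[as.integer(names(tab))] + as.numeric(tab) * ps2
    }
    cid <- hex_locate(grid, deposits$table$x, deposits$table$y)
    tab <- table(cid[!is.na(cid)])
    cnt[as.integer(names(tab))] <- as.integer(tab)
    if (!is.null(land_mask)) {
      lm <- if (inherits(land_mask, "mb_raster")) raster_band(land_mask, 1) > 0 else land_mask
      ids <- hex_locate(grid, rep(cc$x, each = length(cc$y)), rep(cc$y, times = length(cc$x)))
      landpx <- tapply(as.vector(lm), ids, sum)
      land <- rep(0, n)
      land[as.integer(names(landpx))] <- as.numeric(landpx) * ps2 / 1e6
    }
  } else {
    cid <- hex_locate(grid, deposits$x, deposits$y)
    ok <- !is.na(cid)
    if (any(ok)) {
      asum <- tapply(deposits$area_m2[ok], cid[ok], sum)
      area[as.integer(names(asum))] <- as.numeric(asum)
      tab <- table(cid[ok])
      cnt[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  grid$stats <- data.frame(id = grid$cells$id, wood_area_m2 = area,
                           deposit_count = cnt, land_area_km2 = land,
                           cover_fraction = ifelse(land > 0, area / (land * 1e6), NA),
                           density_per_km2 = ifelse(land > 0, cnt / land, NA))
  grid
}

#' Assign deposits to forested source catchments
#'
#' A deposit in a forested catchment keeps it; deposits in catchments without
#' forest cover are reassigned to the forested catchment whose coastal outlet
#' is nearest along the coastline (reassignment happens at the catchment
#' level, so all deposits of a non-forested catchment move together).
#'
#' @param deposits a `deposit_set` or data.frame with `x`, `y`.
#' @param catchments data.frame with `id`, `x_min`, `x_max`,
#'   `forest_fraction`, `outlet_s` (outlet arclength along the coastline).
#' @param forest_threshold catchments with `forest_fraction` at or below this
#'   are treated as non-forested (default 0).
#' @return data.frame of the deposit table with `catchment_id` (containing
#'   catchment) and `source_catchment_id` (after reassignment).
#' @export
assign_catchments <- function(deposits, catchments, forest_threshold = 0) {
  tb <- if (inherits(deposits, "deposit_set")) deposits$table else deposits
  forested <- catchments$forest_fraction > forest_threshold
  if (!any(forested)) stop_config("no forested catchment available for assignment")
  idx <- findInterval(tb$x, c(catchments$x_min[1], catchments$x_max),
                      rightmost.closed = TRUE, all.inside = TRUE)
  cid <- catchments$id[idx]
  remap <- catchments$id
  for (k in which(!forested)) {
    d <- abs(catchments$outlet_s[forested] - catchments$outlet_s[k])
    remap[k] <- catchments$id[forested][which.min(d)]
  }
  tb$catchment_id <- cid
  tb$source_catchment_id <- remap[match(cid, catchments$id)]
  tb
}

#' Distance decay of deposit cover from river mouths
#'
#' Computes the planar distance from each deposit centroid to the nearest
#' qualifying river mouth, the area-weighted cumulative cover curve, a
#' `fraction_within(radius_km)` lookup, and deposit cover binned by distance
#' (used for the cover-vs-distance rank correlation).
#'
#' @param deposits a `deposit_set` or data.frame with `x`, `y`, `area_m2`.
#' @param mouths data.frame with `x`, `y` of qualifying (forested-catchment)
#'   mouths.
#' @param bin_km width of distance bins for the binned cover summary.
#' @return list with `distances_km`, `curve` (data.frame `d_km`,
#'   `cum_fraction`), `fraction_within` (function of radius in km), and
#'   `binned` (data.frame `d_mid_km`, `area_m2`).
#' @export
distance_decay <- function(deposits, mouths, bin_km = 10) {
  tb <- if (inherits(deposits, "deposit_set")) deposits$table else deposits
  if (!nrow(mouths)) stop_config("distance_decay: need >= 1 mouth")
  if (!nrow(tb))
    return(list(distances_km = numeric(0),
                curve = data.frame(d_km = numeric(0), cum_fraction = numeric(0)),
                fraction_within = function(r) NA_real_,
                binned = data.frame(d_mid_km = numeric(0), area_m2 = numeric(0))))
  d2 <- outer(tb$x, mouths$x, "-")^2 + outer(tb$y, mouths$y, "-")^2
  dk <- sqrt(apply(d2, 1, min)) / 1000
  ord <- order(dk)
  total <- sum(tb$area_m2)
  curve <- data.frame(d_km = dk[ord], cum_fraction = cumsum(tb$area_m2[ord]) / total)
  fw <- function(r) if (!length(r)) numeric(0) else
    vapply(r, function(ri) sum(tb$area_m2[dk <= ri]) / total, 0)
  bins <- seq(0, max(dk) + bin_km, by = bin_km)
  bi <- findInterval(dk, bins, rightmost.closed = TRUE)
  ba <- tapply(tb$area_m2, factor(bi, levels = seq_len(length(bins) - 1L)), sum)
  ba[is.na(ba)] <- 0
  list(distances_km = dk, curve = curve, fraction_within = fw,
       binned = data.frame(d_mid_km = (bins[-length(bins)] + bins[-1]) / 2,
                           area_m2 = as.numeric(ba)))
}
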