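# Planar vector geometry on a local metric CRS. Polygons are lists of rings;
# each ring a two-column matrix (x, y), not closed (first vertex not repeated).
# Ring 1 is the exterior; further rings are holes (even-odd semantics).

#' Signed area of a polygon ring (shoelace formula)
#' @param ring two-column matrix of vertices (x, y), not closed.
#' @return Signed planar area; positive for counter-clockwise rings.
#' @export
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Planar area of a polygon with holes
#' @param rings list of rings (exterior first).
#' @export
polygon_area <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  abs(ring_area(rings[[1]])) - sum(vapply(rings[-1], function(r) abs(ring_area(r)), 0))
}

#' Even-odd point-in-polygon test (vectorised over points)
#' @param px,py point coordinates.
#' @param rings list of rings or a single ring matrix; crossings are counted
#'   over all rings, so holes are excluded automatically.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    x <- ring[, 1]; y <- ring[, 2]
    n <- length(x)
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
  }
  inside
}

#' Rasterize polygons onto a raster grid
#'
#' A pixel belongs to a polygon iff its centre lies inside (even-odd rule).
#' Later polygons overwrite earlier ones where they overlap.
#'
#' @param polys list of polygons (each a list of rings).
#' @param template an `mb_raster` defining the grid.
#' @param values numeric value to burn per polygon (recycled).
#' @param background value for untouched pixels.
#' @return A matrix of burned values on the template grid.
#' @export
rasterize_polygons <- function(polys, template, values = seq_along(polys),
                               background = 0) {
  out <- matrix(background, raster_nrow(template), raster_ncol(template))
  if (length(polys) == 0L) return(out)
  values <- rep_len(values, length(polys))
  cc <- raster_coords(template)
  ps <- template$pixel_size
  for (i in seq_along(polys)) {
    rings <- polys[[i]]
    if (is.matrix(rings)) rings <- list(rings)
    allv <- do.call(rbind, rings)
    cr <- range(allv[, 1]); rr <- range(allv[, 2])
    ci <- which(cc$x >= cr[1] - ps & cc$x <= cr[2] + ps)
    ri <- which(cc$y >= rr[1] - ps & cc$y <= rr[2] + ps)
    if (!length(ci) || !length(ri)) next
    g <- expand.grid(r = ri, c = ci)
    hit <- point_in_polygon(cc$x[g$c], cc$y[g$r], rings)
    if (any(hit)) out[cbind(g$r[hit], g$c[hit])] <- values[i]
  }
  out
}

#' Label connected components of a binary mask
#'
#' 4-connected labeling via \code{EBImage::bwlabel}; for 8-connectivity,
#' diagonally adjacent 4-components are merged with a union-find pass.
#'
#' @param mask logical or 0/1 matrix (`NA` treated as background).
#' @param connectivity 4 or 8.
#' @return Integer label matrix (0 = background), labels contiguous from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- mask
  m[is.na(m)] <- 0
  lab <- EBImage::bwlabel(matrix(as.numeric(m != 0), nrow(m), ncol(m)))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab == 0L || connectivity == 4) return(lab)
  # union-find over diagonal label adjacencies
  parent <- seq_len(nlab)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(m); nc <- ncol(m)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- findp(pairs[k, 1]); b <- findp(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), findp, 1L)
  relab <- match(root, sort(unique(root)))
  lab[lab > 0] <- relab[lab[lab > 0]]
  lab
}

#' Count interior holes of a binary region
#'
#' Holes are 4-connected background components fully enclosed by the region
#' (the topological dual of 8-connected foreground).
#'
#' @param mask logical matrix, `TRUE` = region.
#' @return Integer hole count.
#' @export
count_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask & !is.na(mask)
  bg <- label_components(!pad, connectivity = 4)
  border <- unique(c(bg[1, ], bg[nr + 2L, ], bg[, 1], bg[, nc + 2L]))
  length(setdiff(unique(as.vector(bg)), c(0L, border)))
}

#' Trace polygon rings along pixel edges of a binary region
#'
#' Produces exact rectilinear rings following pixel boundaries: the exterior
#' ring is counter-clockwise, holes clockwise, and the signed areas sum to
#' pixel count times pixel area. Pinch points (diagonal contacts of an
#' 8-connected region) are resolved by always taking the sharpest right turn,
#' which keeps the region on the left of every directed edge.
#'
#' @param mask logical matrix, `TRUE` = region (a single component is typical
#'   but not required; rings of all components are returned).
#' @param template `mb_raster` giving the georeference of `mask`'s grid.
#' @return List of rings (two-column world-coordinate matrices), exteriors
#'   counter-clockwise.
#' @export
trace_rings <- function(mask, template) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask & !is.na(mask)
  occ <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc & m[cbind(pmax(pmin(r, nr), 1), pmax(pmin(c, nc), 1))]
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  # vertices keyed on integer corner grid: corner (i, j), i in 0..nr (top->bottom), j in 0..nc
  vkey <- function(i, j) i * (nc + 1L) + j
  r <- idx[, 1]; c <- idx[, 2]
  edges <- list()
  add <- function(i1, j1, i2, j2, take) {
    if (any(take)) edges[[length(edges) + 1L]] <<- cbind(vkey(i1[take], j1[take]), vkey(i2[take], j2[take]))
  }
  # directed so the region is on the LEFT in world coordinates (y up):
  # exterior rings come out counter-clockwise, hole rings clockwise
  add(r - 1L, c,      r - 1L, c - 1L, !occ(r - 1L, c))  # top edge, westward
  add(r,      c - 1L, r,      c,      !occ(r + 1L, c))  # bottom edge, eastward
  add(r - 1L, c - 1L, r,      c - 1L, !occ(r, c - 1L))  # left edge, southward
  add(r,      c,      r - 1L, c,      !occ(r, c + 1L))  # right edge, northward
  E <- do.call(rbind, edges)
  from <- E[, 1]; to <- E[, 2]
  used <- rep(FALSE, length(from))
  ord <- order(from)
  from_s <- from[ord]
  starts <- match(unique(from_s), from_s)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  uf <- unique(from_s)
  for (k in seq_along(uf)) {
    i1 <- starts[k]
    i2 <- if (k < length(uf)) starts[k + 1L] - 1L else length(from_s)
    assign(as.character(uf[k]), ord[i1:i2], envir = lookup)
  }
  dirvec <- function(a, b) { # corner key -> (di, dj)
    ai <- a %/% (nc + 1L); aj <- a %% (nc + 1L)
    bi <- b %/% (nc + 1L); bj <- b %% (nc + 1L)
    c(bi - ai, bj - aj)
  }
  rings <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    path <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      path <- c(path, e)
      nxt_cands <- get0(as.character(to[e]), envir = lookup, ifnotfound = integer(0))
      nxt_cands <- nxt_cands[!used[nxt_cands]]
      if (!length(nxt_cands)) break
      if (length(nxt_cands) == 1L) { e <- nxt_cands } else {
        # pinch point (diagonal contact): take the sharpest right turn, which
        # carries the trace across the pinch and keeps an 8-connected region
        # on a single exterior ring (background stays 4-connected)
        d0 <- dirvec(from[e], to[e])
        score <- vapply(nxt_cands, function(ne) {
          d1 <- dirvec(from[ne], to[ne])
          # = -(world cross product); max picks the sharpest right turn
          d0[2] * d1[1] - d0[1] * d1[2]
        }, 0)
        e <- nxt_cands[which.max(score)]
      }
    }
    keys <- c(from[path], to[path[length(path)]])
    if (keys[1] == keys[length(keys)]) keys <- keys[-length(keys)]
    ii <- keys %/% (nc + 1L); jj <- keys %% (nc + 1L)
    ring <- cbind(template$xmin + jj * template$pixel_size,
                  template$ymax - ii * template$pixel_size)
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}

#' Vectorize one labelled component into a polygon with holes
#' @param mask logical matrix of the component.
#' @param template `mb_raster` georeference.
#' @return list of rings, exterior (largest |area|, made CCW) first, holes CW.
#' @export
component_polygon <- function(mask, template) {
  rings <- trace_rings(mask, template)
  if (!length(rings)) return(list())
  areas <- vapply(rings, ring_area, 0)
  ext <- which.max(abs(areas))
  orient <- function(ring, ccw) {
    a <- ring_area(ring)
    if ((a > 0) != ccw) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
  }
  out <- c(list(orient(rings[[ext]], TRUE)),
           lapply(rings[-ext], orient, ccw = FALSE))
  out
}

# ---- polylines ----------------------------------------------------------

#' Cumulative arclength of a polyline
#' @param line two-column matrix of vertices.
#' @export
polyline_length <- function(line) {
  d <- sqrt(rowSums(diff(line)^2))
  c(0, cumsum(d))
}

#' Project points onto a polyline
#' @param px,py point coordinates.
#' @param line two-column matrix of polyline vertices.
#' @return data.frame with `s` (arclength of the nearest point on the line)
#'   and `dist` (Euclidean distance to it).
#' @export
project_to_polyline <- function(px, py, line) {
  cs <- polyline_length(line)
  n <- nrow(line) - 1L
  best_d2 <- rep(Inf, length(px)); best_s <- rep(NA_real_, length(px))
  for (k in seq_len(n)) {
    ax <- line[k, 1]; ay <- line[k, 2]
    bx <- line[k + 1L, 1]; by <- line[k + 1L, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx^2 + vy^2
    t <- if (L2 == 0) rep(0, length(px)) else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / L2, 0), 1)
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- cs[k] + t[upd] * sqrt(L2)
  }
  data.frame(s = best_s, dist = sqrt(best_d2))
}

# ---- GeoJSON ------------------------------------------------------------

geojson_polygon <- function(rings) {
  lapply(rings, function(r) {
    r <- rbind(r, r[1, , drop = FALSE])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  })
}

#' Write features to a GeoJSON file
#'
#' @param geoms list of geometries: each either a polygon (list of ring
#'   matrices), a point (length-2 numeric), or a polyline (two-column matrix
#'   tagged with attribute `type = "LineString"`).
#' @param properties data.frame of per-feature attributes (or NULL).
#' @param path output path.
#' @export
write_geojson <- function(geoms, properties = NULL, path) {
  feats <- lapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    geom <- if (is.numeric(g) && length(g) == 2L) {
      list(type = "Point", coordinates = c(g[1], g[2]))
    } else if (is.matrix(g)) {
      if (identical(attr(g, "type"), "LineString"))
        list(type = "LineString",
             coordinates = lapply(seq_len(nrow(g)), function(k) c(g[k, 1], g[k, 2])))
      else list(type = "Polygon", coordinates = geojson_polygon(list(g)))
    } else list(type = "Polygon", coordinates = geojson_polygon(g))
    props <- if (is.null(properties)) structure(list(), names = character(0)) else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", geometry = geom, properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats), path,
                       auto_unbox = TRUE, digits = 10)
  invisible(path)
}
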