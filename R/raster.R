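#' Multiband georeferenced raster
#'
#' A lightweight in-memory raster: a numeric array `[row, col, band]` on a
#' square-pixel grid in a projected, metric coordinate system. Row 1 is the
#' northernmost row; `NA` encodes nodata. All distances and areas in the
#' package are planar metres, so a single local metric CRS suffices.
#'
#' @param values numeric matrix (one band) or 3-D array `[rows, cols, bands]`.
#' @param xmin x coordinate of the western (left) edge, metres.
#' @param ymax y coordinate of the northern (top) edge, metres.
#' @param pixel_size pixel edge length in metres (square pixels).
#' @param bands optional character band labels, e.g. `c("B","G","R","NIR")`.
#' @param crs character tag for the coordinate system (informational).
#' @return An object of class `mb_raster`.
#' @export
mb_raster <- function(values, xmin = 0, ymax = NULL, pixel_size = 1,
                      bands = NULL, crs = "local-metres") {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L, pixel_size > 0)
  if (is.null(ymax)) ymax <- dim(values)[1] * pixel_size
  if (is.null(bands)) bands <- paste0("band", seq_len(dim(values)[3]))
  stopifnot(length(bands) == dim(values)[3])
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 pixel_size = pixel_size, bands = bands, crs = crs),
            class = "mb_raster")
}

#' @export
print.mb_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<mb_raster> %d x %d pixels, %d band(s) [%s]\n", d[1], d[2], d[3],
              paste(x$bands, collapse = ",")))
  cat(sprintf("  pixel %g m; extent x [%g, %g], y [%g, %g]; %d NA cells\n",
              x$pixel_size, x$xmin, x$xmin + d[2] * x$pixel_size,
              x$ymax - d[1] * x$pixel_size, x$ymax, sum(is.na(x$values))))
  invisible(x)
}

#' @rdname mb_raster
#' @param x an `mb_raster`.
#' @export
raster_nrow <- function(x) dim(x$values)[1]
#' @rdname mb_raster
#' @export
raster_ncol <- function(x) dim(x$values)[2]
#' @rdname mb_raster
#' @export
raster_nband <- function(x) dim(x$values)[3]

#' @rdname mb_raster
#' @export
raster_extent <- function(x) {
  c(xmin = x$xmin, xmax = x$xmin + raster_ncol(x) * x$pixel_size,
    ymin = x$ymax - raster_nrow(x) * x$pixel_size, ymax = x$ymax)
}

#' Pixel-centre coordinates of a raster
#' @param x an `mb_raster`.
#' @return list with vectors `x` (per column) and `y` (per row).
#' @export
raster_coords <- function(x) {
  list(x = x$xmin + (seq_len(raster_ncol(x)) - 0.5) * x$pixel_size,
       y = x$ymax - (seq_len(raster_nrow(x)) - 0.5) * x$pixel_size)
}

#' Convert world coordinates to (row, col) indices
#' @param x an `mb_raster`.
#' @param px,py numeric world coordinates.
#' @return integer matrix with columns `row`, `col`; coordinates outside the
#'   grid yield `NA`.
#' @export
world_to_pixel <- function(x, px, py) {
  col <- floor((px - x$xmin) / x$pixel_size) + 1L
  row <- floor((x$ymax - py) / x$pixel_size) + 1L
  bad <- col < 1L | col > raster_ncol(x) | row < 1L | row > raster_nrow(x)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract one band as a matrix
#' @param x an `mb_raster`.
#' @param band band index or label.
#' @export
raster_band <- function(x, band) {
  if (is.character(band)) band <- match(band, x$bands)
  x$values[, , band, drop = TRUE]
}

#' Do two rasters share the same grid?
#' @param a,b `mb_raster` objects.
#' @param tol numeric tolerance in metres.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  isTRUE(all(dim(a$values)[1:2] == dim(b$values)[1:2])) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$pixel_size - b$pixel_size) < tol
}

#' Crop a raster to a rectangular window of pixels
#' @param x an `mb_raster`.
#' @param rows,cols integer index ranges.
#' @export
raster_crop <- function(x, rows, cols) {
  mb_raster(x$values[rows, cols, , drop = FALSE],
            xmin = x$xmin + (min(cols) - 1L) * x$pixel_size,
            ymax = x$ymax - (min(rows) - 1L) * x$pixel_size,
            pixel_size = x$pixel_size, bands = x$bands, crs = x$crs)
}

#' Block-mean aggregation to a coarser grid
#'
#' Aggregates by averaging `factor x factor` pixel blocks; the extent is
#' preserved (trailing partial blocks are averaged over the pixels present).
#'
#' @param x an `mb_raster`.
#' @param factor integer aggregation factor (>= 1).
#' @export
block_mean <- function(x, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(x)
  nr <- raster_nrow(x); nc <- raster_ncol(x)
  ri <- ceiling(seq_len(nr) / factor); ci <- ceiling(seq_len(nc) / factor)
  nro <- max(ri); nco <- max(ci)
  out <- array(NA_real_, dim = c(nro, nco, raster_nband(x)))
  for (b in seq_len(raster_nband(x))) {
    m <- x$values[, , b]
    g <- rowsum(m, ri, na.rm = TRUE)
    cnt <- rowsum((!is.na(m)) * 1, ri)
    g <- t(rowsum(t(g), ci, na.rm = TRUE))
    cnt <- t(rowsum(t(cnt), ci))
    v <- g / cnt
    v[cnt == 0] <- NA_real_
    out[, , b] <- v
  }
  mb_raster(out, xmin = x$xmin, ymax = x$ymax,
            pixel_size = x$pixel_size * factor, bands = x$bands, crs = x$crs)
}

# Keys cubic-convolution kernel (a = -0.5), the standard bicubic kernel.
# Reproduces linear functions exactly in the interior.
keys_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  w <- numeric(length(t))
  i1 <- t <= 1
  w[i1] <- (a + 2) * t[i1]^3 - (a + 3) * t[i1]^2 + 1
  i2 <- t > 1 & t < 2
  w[i2] <- a * t[i2]^3 - 5 * a * t[i2]^2 + 8 * a * t[i2] - 4 * a
  w
}

# 1-D cubic interpolation matrix mapping n input samples (centres at 0..n-1)
# to output positions u (fractional, same coordinate frame). Edge-replicated.
cubic_weights <- function(u, n) {
  A <- matrix(0, length(u), n)
  i0 <- floor(u)
  for (k in -1:2) {
    idx <- i0 + k
    w <- keys_kernel(u - idx)
    idx <- pmin(pmax(idx, 0), n - 1)
    A[cbind(seq_along(u), idx + 1)] <- A[cbind(seq_along(u), idx + 1)] + w
  }
  # normalise so constants are reproduced exactly at the edges too
  A / rowSums(A)
}

#' Resample a raster to a new pixel size by bicubic interpolation
#'
#' Separable cubic-convolution (Keys kernel, a = -0.5) over the same extent.
#' Labels or masks should be resampled with `method = "nearest"` instead, which
#' preserves the value set.
#'
#' @param x an `mb_raster`.
#' @param pixel_size target pixel size in metres.
#' @param method `"bicubic"` (default) or `"nearest"`.
#' @export
raster_resample <- function(x, pixel_size, method = c("bicubic", "nearest")) {
  method <- match.arg(method)
  stopifnot(pixel_size > 0)
  ext <- raster_extent(x)
  nro <- max(1L, round((ext["ymax"] - ext["ymin"]) / pixel_size))
  nco <- max(1L, round((ext["xmax"] - ext["xmin"]) / pixel_size))
  # output pixel centres in input fractional index coordinates (0-based)
  ux <- (x$xmin + (seq_len(nco) - 0.5) * pixel_size - x$xmin) / x$pixel_size - 0.5
  uy <- (x$ymax - (x$ymax - (seq_len(nro) - 0.5) * pixel_size)) / x$pixel_size - 0.5
  out <- array(NA_real_, dim = c(nro, nco, raster_nband(x)))
  if (method == "nearest") {
    ri <- pmin(pmax(round(uy) + 1, 1), raster_nrow(x))
    ci <- pmin(pmax(round(ux) + 1, 1), raster_ncol(x))
    for (b in seq_len(raster_nband(x))) out[, , b] <- x$values[ri, ci, b]
  } else {
    Ar <- cubic_weights(uy, raster_nrow(x))
    Ac <- cubic_weights(ux, raster_ncol(x))
    for (b in seq_len(raster_nband(x))) out[, , b] <- Ar %*% x$values[, , b] %*% t(Ac)
  }
  mb_raster(out, xmin = x$xmin, ymax = x$ymax, pixel_size = pixel_size,
            bands = x$bands, crs = x$crs)
}

#' Write / read a multiband raster as ESRI ASCII grids
#'
#' One plain-text `.asc` file per band (`<stem>_<band>.asc`), georeferenced via
#' the standard ASCII-grid header. A small JSON sidecar (`<stem>.json`) records
#' band order and the CRS tag.
#'
#' @param x an `mb_raster`.
#' @param stem path stem (no extension).
#' @return `write_raster` returns the sidecar path invisibly; `read_raster`
#'   returns an `mb_raster`.
#' @export
write_raster <- function(x, stem) {
  for (b in seq_len(raster_nband(x))) {
    f <- sprintf("%s_%s.asc", stem, x$bands[b])
    m <- x$values[, , b]
    hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
             sprintf("xllcorner %.10g", x$xmin),
             sprintf("yllcorner %.10g", x$ymax - nrow(m) * x$pixel_size),
             sprintf("cellsize %.10g", x$pixel_size),
             "NODATA_value -9999")
    m[is.na(m)] <- -9999
    con <- file(f, "w")
    writeLines(hdr, con)
    utils::write.table(format(m, trim = TRUE, digits = 8), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    close(con)
  }
  side <- sprintf("%s.json", stem)
  jsonlite::write_json(list(bands = x$bands, crs = x$crs, pixel_size = x$pixel_size),
                       side, auto_unbox = TRUE)
  invisible(side)
}

#' @rdname write_raster
#' @export
read_raster <- function(stem) {
  side <- jsonlite::read_json(sprintf("%s.json", stem), simplifyVector = TRUE)
  mats <- lapply(side$bands, function(b) {
    f <- sprintf("%s_%s.asc", stem, b)
    hdr <- readLines(f, n = 6)
    val <- as.numeric(sub("^\\S+\\s+", "", hdr))
    names(val) <- tolower(sub("\\s.*$", "", hdr))
    m <- as.matrix(utils::read.table(f, skip = 6))
    dimnames(m) <- NULL
    m[m == val["nodata_value"]] <- NA_real_
    list(m = m, hdr = val)
  })
  hdr <- mats[[1]]$hdr
  arr <- array(NA_real_, dim = c(hdr["nrows"], hdr["ncols"], length(mats)))
  for (b in seq_along(mats)) arr[, , b] <- mats[[b]]$m
  mb_raster(arr, xmin = hdr[["xllcorner"]],
            ymax = hdr[["yllcorner"]] + hdr[["nrows"]] * hdr[["cellsize"]],
            pixel_size = hdr[["cellsize"]], bands = side$bands, crs = side$crs)
}
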