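# Evaluation of coarse-resolution predictions against a high-resolution
# reference segmentation: paired-cell regression on a square grid, overall
# relative bias, and size-stratified error with overlap-based matching.

square_cell_areas <- function(dep, origin, cell) {
  # returns data.frame cell_key -> area for a deposit_set or table
  if (inherits(dep, "deposit_set")) {
    tpl <- dep$template
    cc <- raster_coords(tpl)
    ps2 <- tpl$pixel_size^2
    px <- unlist(dep$cells, use.names = FALSE)
    if (!length(px)) return(data.frame(key = character(0), area = numeric(0)))
    rc <- arrayInd(px, c(raster_nrow(tpl), raster_ncol(tpl)))
    keyv <- paste(floor((cc$x[rc[, 2]] - origin[1]) / cell),
                  floor((cc$y[rc[, 1]] - origin[2]) / cell))
    ag <- tapply(rep(ps2, length(keyv)), keyv, sum)
    data.frame(key = names(ag), area = as.numeric(ag), stringsAsFactors = FALSE)
  } else {
    kx <- floor((dep$x - origin[1]) / cell)
    ky <- floor((dep$y - origin[2]) / cell)
    ag <- tapply(dep$area_m2, paste(kx, ky), sum)
    data.frame(key = names(ag), area = as.numeric(ag), stringsAsFactors = FALSE)
  }
}

#' Compare predicted and reference deposits on a square grid
#'
#' Deposit area is aggregated into `cell_size_m` square cells (origin aligned
#' to the reference grid by default); cells covered by either dataset enter
#' an ordinary least-squares regression of predicted on reference area
#' (free intercept, with the zero-intercept slope also reported) and the
#' overall relative bias `100 * (sum pred - sum ref) / sum ref`. The bias
#' with reference deposits smaller than `mmu_m2` excluded is reported
#' alongside.
#'
#' @param pred_deposits,ref_deposits `deposit_set`s or data.frames with
#'   `x`, `y`, `area_m2`.
#' @param cell_size_m evaluation cell size (default 512).
#' @param origin grid origin `c(x, y)` (default `c(0, 0)`).
#' @param mmu_m2 minimum-mapping-unit cutoff for the exclusion bias
#'   (default 100).
#' @return An `eval_report` list: `cells` (paired areas), `r_squared`,
#'   `slope`, `slope_zero_intercept`, `intercept`,
#'   `relative_bias_percent`, `relative_bias_excl_small_percent`,
#'   `n_cells`, `flags`.
#' @export
grid_compare <- function(pred_deposits, ref_deposits, cell_size_m = 512,
                         origin = c(0, 0), mmu_m2 = 100) {
  pa <- square_cell_areas(pred_deposits, origin, cell_size_m)
  ra <- square_cell_areas(ref_deposits, origin, cell_size_m)
  keys <- union(pa$key, ra$key)
  pred <- pa$area[match(keys, pa$key)]; pred[is.na(pred)] <- 0
  ref <- ra$area[match(keys, ra$key)]; ref[is.na(ref)] <- 0
  flags <- character(0)
  tot_ref <- sum(ref)
  rb <- if (tot_ref > 0) 100 * (sum(pred) - tot_ref) / tot_ref else {
    flags <- c(flags, "zero_reference_area"); NA_real_
  }
  # reference with sub-MMU deposits excluded
  ref_tb <- if (inherits(ref_deposits, "deposit_set")) ref_deposits$table else ref_deposits
  rb_excl <- NA_real_
  if (nrow(ref_tb)) {
    big <- ref_tb[ref_tb$area_m2 >= mmu_m2, , drop = FALSE]
    tot_big <- sum(big$area_m2)
    if (tot_big > 0) rb_excl <- 100 * (sum(pred) - tot_big) / tot_big
  }
  if (length(keys) >= 3 && stats::var(ref) > 0) {
    fit <- stats::lm(pred ~ ref)
    # a perfect fit is a legitimate outcome on synthetic identity checks
    r2 <- suppressWarnings(summary(fit)$r.squared)
    slope <- unname(stats::coef(fit)[2]); icpt <- unname(stats::coef(fit)[1])
    slope0 <- sum(pred * ref) / sum(ref^2)
  } else {
    flags <- c(flags, "degenerate_regression")
    r2 <- NA_real_; slope <- NA_real_; icpt <- NA_real_
    slope0 <- if (sum(ref^2) > 0) sum(pred * ref) / sum(ref^2) else NA_real_
  }
  structure(list(cells = data.frame(key = keys, pred_m2 = pred, ref_m2 = ref),
                 r_squared = r2, slope = slope, intercept = icpt,
                 slope_zero_intercept = slope0,
                 relative_bias_percent = rb,
                 relative_bias_excl_small_percent = rb_excl,
                 n_cells = length(keys), cell_size_m = cell_size_m,
                 flags = flags),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d cells of %g m: r2 %.3f, slope %.3f, bias %.2f%%\n",
              x$n_cells, x$cell_size_m, x$r_squared, x$slope,
              x$relative_bias_percent))
  invisible(x)
}

match_by_overlap <- function(pred, ref) {
  # maximal pixel-overlap matching of prediction deposits to reference
  # deposits (both deposit_sets on grids over the same CRS)
  stopifnot(inherits(pred, "deposit_set"), inherits(ref, "deposit_set"))
  rt <- ref$template
  assign_of <- function(dep) {
    lab <- matrix(0L, raster_nrow(rt), raster_ncol(rt))
    for (i in seq_len(nrow(ref$table))) lab[ref$cells[[i]]] <- i
    cc <- raster_coords(dep$template)
    vapply(seq_len(nrow(dep$table)), function(i) {
      rc <- arrayInd(dep$cells[[i]], c(raster_nrow(dep$template), raster_ncol(dep$template)))
      px <- world_to_pixel(rt, cc$x[rc[, 2]], cc$y[rc[, 1]])
      ok <- !is.na(px[, 1])
      if (!any(ok)) return(0L)
      hits <- lab[px[ok, , drop = FALSE]]
      hits <- hits[hits > 0L]
      if (!length(hits)) 0L else as.integer(names(which.max(table(hits))))
    }, 0L)
  }
  assign_of(pred)
}

# fraction of each reference deposit's area covered by predicted pixels
ref_pixel_coverage <- function(pred, ref) {
  pt <- pred$template
  pm <- matrix(FALSE, raster_nrow(pt), raster_ncol(pt))
  pm[unlist(pred$cells)] <- TRUE
  cc <- raster_coords(ref$template)
  vapply(seq_len(nrow(ref$table)), function(i) {
    rc <- arrayInd(ref$cells[[i]], c(raster_nrow(ref$template), raster_ncol(ref$template)))
    px <- world_to_pixel(pt, cc$x[rc[, 2]], cc$y[rc[, 1]])
    ok <- !is.na(px[, 1])
    if (!any(ok)) return(0)
    mean(pm[px[ok, , drop = FALSE]])
  }, 0)
}

#' Size-stratified relative bias
#'
#' Reference deposits are binned by area (default edges 100 and 10,000 m2);
#' predicted deposits are matched to reference deposits by greatest pixel
#' overlap, unmatched predictions are pooled into a commission line. Per-bin
#' bias is `100 * (matched predicted area - reference bin area) / reference
#' bin area`. Because a slightly dilated but correct prediction can be
#' matched onto a tiny reference feature it merely touches, the per-bin
#' `ref_coverage` column reports omission directly: the area-weighted
#' fraction of the bin's reference pixels covered by predicted pixels. The
#' share of reference area below the smallest edge is attached (the part of
#' the error attributable to sub-minimum-mapping-unit deposits).
#'
#' @param pred_deposits,ref_deposits `deposit_set`s on grids in the same
#'   coordinate system.
#' @param bin_edges interior bin edges in m2 (default `c(100, 10000)`).
#' @return data.frame with one row per bin plus a `commission` row; attribute
#'   `share_below_first_edge`.
#' @export
size_stratified_bias <- function(pred_deposits, ref_deposits,
                                 bin_edges = c(100, 10000)) {
  ref_tb <- ref_deposits$table
  edges <- c(0, bin_edges, Inf)
  labels <- paste0("(", edges[-length(edges)], ",", edges[-1], "]")
  match_id <- match_by_overlap(pred_deposits, ref_deposits)
  pred_area_by_ref <- numeric(nrow(ref_tb))
  if (nrow(pred_deposits$table)) {
    ag <- tapply(pred_deposits$table$area_m2[match_id > 0], match_id[match_id > 0], sum)
    pred_area_by_ref[as.integer(names(ag))] <- as.numeric(ag)
  }
  commission <- sum(pred_deposits$table$area_m2[match_id == 0])
  coverage <- ref_pixel_coverage(pred_deposits, ref_deposits)
  bin_of <- cut(ref_tb$area_m2, edges, labels = labels)
  out <- do.call(rbind, lapply(seq_along(labels), function(k) {
    sel <- !is.na(bin_of) & bin_of == labels[k]
    ra <- sum(ref_tb$area_m2[sel]); pa <- sum(pred_area_by_ref[sel])
    cov <- if (ra > 0) sum(coverage[sel] * ref_tb$area_m2[sel]) / ra else NA_real_
    data.frame(bin = labels[k], ref_area_m2 = ra, pred_area_m2 = pa,
               bias_percent = if (ra > 0) 100 * (pa - ra) / ra else NA_real_,
               ref_coverage = cov, ref_share = NA_real_, empty = ra == 0)
  }))
  tot <- sum(ref_tb$area_m2)
  out$ref_share <- if (tot > 0) out$ref_area_m2 / tot else NA_real_
  out <- rbind(out, data.frame(bin = "commission", ref_area_m2 = 0,
                               pred_area_m2 = commission, bias_percent = NA_real_,
                               ref_coverage = NA_real_, ref_share = NA_real_,
                               empty = commission == 0))
  attr(out, "share_below_first_edge") <-
    if (tot > 0) sum(ref_tb$area_m2[ref_tb$area_m2 < bin_edges[1]]) / tot else NA_real_
  out
}
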