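test_that("presence probability counts detections over observed years", {
  m <- function(...) matrix(c(...), 1, 1)
  expect_equal(presence_probability(list(m(1), m(1), m(1)))[1, 1], 1)
  expect_equal(presence_probability(list(m(1), m(1), m(0)))[1, 1], 2 / 3)
  p <- presence_probability(list(m(1), m(0), m(0)))[1, 1]
  expect_equal(p, 1 / 3)
  expect_lt(p, 0.6)                       # fails the presence threshold
  # unobserved years leave the denominator
  expect_equal(presence_probability(list(m(1), m(NA), m(0)))[1, 1], 1 / 2)
  expect_true(is.na(presence_probability(list(m(NA), m(NA)))[1, 1]))
  expect_error(presence_probability(list(m(1))), ">= 2")
})

test_that("dual-threshold fusion reduces to year-count rules (exhaustive n=2,3,4)", {
  for (n in 2:4) {
    hist <- as.matrix(expand.grid(rep(list(0:1), n)))
    for (k in seq_len(nrow(hist))) {
      p <- mean(hist[k, ])
      # presence (seeds) at >= 0.6; shape at >= 0.5
      expect_equal(p >= 0.6, sum(hist[k, ]) >= ceiling(0.6 * n))
      expect_equal(p >= 0.5, sum(hist[k, ]) >= ceiling(0.5 * n))
    }
  }
})

test_that("seeded-component extraction follows the presence/shape contract", {
  tpl <- rast(matrix(0, 1, 4), ps = 3)
  # (1.0, 0.5, 0.5, 0.0): one deposit spanning the first three pixels
  d <- extract_deposits(matrix(c(1, 0.5, 0.5, 0), 1, 4), template = tpl)
  expect_equal(nrow(d$table), 1L)
  expect_equal(d$table$n_pixels, 3L)
  expect_equal(d$table$area_m2, 27)
  # no seed -> no deposit
  d0 <- extract_deposits(matrix(c(0.5, 0.5), 1, 2), template = rast(matrix(0, 1, 2)))
  expect_equal(nrow(d0$table), 0L)
  expect_error(extract_deposits(matrix(1, 1, 1), t_presence = 0.5, t_shape = 0.6,
                                template = tpl), "thresholds")
})

test_that("three-year probabilities make shape and presence sets coincide", {
  # attainable values {0, 1/3, 2/3, 1}: 2/3 >= 0.6 and 1/3 < 0.5
  set.seed(8)
  masks <- lapply(1:3, function(i) matrix(rbinom(100, 1, 0.4), 10, 10))
  prob <- presence_probability(masks)
  expect_setequal(unique(round(as.vector(prob), 6)), round(c(0, 1/3, 2/3, 1), 6))
  expect_identical(prob >= 0.6, prob >= 0.5)
})

test_that("extraction is monotone in the shape threshold", {
  set.seed(9)
  tpl <- rast(matrix(0, 12, 12))
  pm <- matrix(sample(c(0, 1/3, 2/3, 1), 144, replace = TRUE, prob = c(.55, .2, .15, .1)), 12, 12)
  lo <- extract_deposits(pm, t_shape = 0.3, template = tpl)
  hi <- extract_deposits(pm, t_shape = 0.5, template = tpl)
  # lowering t_shape never loses pixels: every hi pixel is in some lo deposit
  expect_true(all(unlist(hi$cells) %in% unlist(lo$cells)))
  expect_gte(sum(lo$table$area_m2), sum(hi$table$area_m2))
  # vectorization never creates area beyond the shape mask
  expect_lte(sum(lo$table$area_m2), sum(pm >= 0.3) * 9)
})

test_that("water persistence mask uses a strict 20% rule", {
  m <- function(...) matrix(c(...), 1, 1)
  expect_true(build_water_mask(list(m(1), m(0), m(0)))[1, 1] == 1)   # 1/3 > 0.2
  expect_false(build_water_mask(list(m(0), m(0), m(0)))[1, 1] == 1)
  expect_true(build_water_mask(list(m(1), m(1), m(1)))[1, 1] == 1)
  # exactly at the threshold is NOT water (strictly greater)
  expect_false(build_water_mask(list(m(1), m(0), m(0), m(0), m(0)))[1, 1] == 1)
  expect_error(build_water_mask(list()), "empty")
})

test_that("deposit filters apply water, infrastructure and hole rules in order", {
  tpl <- rast(matrix(0, 12, 40), ps = 3)
  mask <- matrix(FALSE, 12, 40)
  mask[2:5, 2:5] <- TRUE                          # A: wet deposit
  mask[2:5, 10:13] <- TRUE                        # B: touches a building
  mask[2:10, 20:32] <- TRUE                       # C: block with 6 holes
  for (rc in list(c(4, 22), c(4, 25), c(4, 28), c(8, 22), c(8, 25), c(8, 28)))
    mask[rc[1], rc[2]] <- FALSE
  dep <- vectorize_and_measure(mask, tpl)
  water <- matrix(FALSE, 12, 40); water[2:5, 2:3] <- TRUE   # half of A wet
  building <- list(cbind(c(27, 33, 33, 27), c(27, 27, 33, 33)))  # world coords over B
  fl <- filter_deposits(dep, water, list(building),
                        max_water_fraction = 0.2, max_holes = 5)
  expect_equal(sort(fl$removed$rule), sort(c("water", "infrastructure", "holes")))
  expect_equal(nrow(fl$deposits$table), nrow(dep$table) - 3L)
})

test_that("a deposit with exactly five interior rings is kept", {
  n <- 19
  mask <- matrix(TRUE, n, n)
  for (k in 1:5) mask[2 * k + 1, 2 * k + 1] <- FALSE   # 5 isolated holes
  tpl <- rast(matrix(0, n, n))
  dep <- vectorize_and_measure(mask, tpl)
  expect_equal(dep$table$hole_count, 5L)
  fl <- filter_deposits(dep, NULL, NULL, max_holes = 5)
  expect_equal(nrow(fl$deposits$table), 1L)
  # six holes are removed
  mask[13, 3] <- FALSE
  fl6 <- filter_deposits(vectorize_and_measure(mask, tpl), NULL, NULL, max_holes = 5)
  expect_equal(fl6$removed$rule, "holes")
})

test_that("vectorization measures areas and holes exactly", {
  tpl <- rast(matrix(0, 12, 12), ps = 3)
  m <- matrix(FALSE, 12, 12); m[2:11, 2:11] <- TRUE
  d <- vectorize_and_measure(m, tpl)
  expect_equal(d$table$area_m2, 900)
  expect_equal(d$table$hole_count, 0L)
  # 5x5 ring with 3x3 hole: 16 pixels, 144 m2, 1 hole
  m2 <- matrix(FALSE, 7, 7); m2[2:6, 2:6] <- TRUE; m2[3:5, 3:5] <- FALSE
  d2 <- vectorize_and_measure(m2, rast(matrix(0, 7, 7), ps = 3))
  expect_equal(d2$table$area_m2, 144)
  expect_equal(d2$table$hole_count, 1L)
  expect_length(d2$polys[[1]], 2L)        # exterior + interior ring
  # empty raster
  d0 <- vectorize_and_measure(matrix(FALSE, 4, 4), rast(matrix(0, 4, 4)))
  expect_equal(nrow(d0$table), 0L)
})

test_that("perfect-classifier closure: truth deposits are recovered end to end", {
  tr <- small_truth(seed = 11, aerial_log_density_per_km2 = 0)
  # oracle classifier: the truth class map of each year
  masks <- lapply(1:3, function(y) (raster_band(tr$class_maps[[y]], 1) == 4) * 1)
  prob <- presence_probability(masks)
  dep <- extract_deposits(mb_raster(prob, xmin = 0, ymax = 780, pixel_size = 3))
  # reference: truth deposits seen in >= 2 of 3 years
  nyr <- lengths(tr$deposit_years)
  stable <- which(nyr >= 2)
  truth_px <- sort(unique(unlist(lapply(tr$deposit_polys[stable], attr, "cells"))))
  got_px <- sort(unique(unlist(dep$cells)))
  expect_true(all(truth_px %in% got_px))
  # recovered area within a 2-pixel-perimeter tolerance overall: here exact
  expect_equal(sum(dep$table$area_m2),
               length(union(got_px, truth_px)) * 9)
})
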