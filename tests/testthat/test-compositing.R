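test_that("medoid matches the brute-force pairwise-distance oracle", {
  # oracle: observation minimising the summed distance to all others
  brute_medoid <- function(obs, metric = "euclidean") {
    dsum <- vapply(seq_along(obs), function(j)
      sum(vapply(obs, function(o)
        if (metric == "euclidean") sqrt(sum((obs[[j]] - o)^2))
        else sum(abs(obs[[j]] - o)), 0)), 0)
    obs[[which.min(dsum)]]
  }
  cases <- list(list(c(1, 1), c(2, 2), c(10, 10)),
                list(c(0, 5), c(1, 4), c(2, 2), c(9, 9)),
                list(c(3, 3), c(3, 3), c(3, 3)))
  for (obs in cases) {
    st <- spectral_stack(obs)
    got <- medoid_composite(st)$values[1, 1, ]
    expect_equal(got, brute_medoid(obs))
    got_m <- medoid_composite(st, metric = "manhattan")$values[1, 1, ]
    expect_equal(got_m, brute_medoid(obs, "manhattan"))
  }
})

test_that("medoid output is always one of the input observations", {
  set.seed(1)
  stack <- lapply(1:4, function(i)
    mb_raster(array(rnorm(6 * 5 * 3), dim = c(6, 5, 3)), pixel_size = 1))
  med <- medoid_composite(stack)
  for (r in 1:6) for (c in 1:5) {
    v <- med$values[r, c, ]
    match_any <- any(vapply(stack, function(s)
      all(abs(s$values[r, c, ] - v) < 1e-12), TRUE))
    expect_true(match_any)
  }
})

test_that("medoid rejects empty stacks and mismatched grids", {
  expect_error(medoid_composite(list()), "empty")
  a <- mb_raster(matrix(0, 2, 2), pixel_size = 1)
  b <- mb_raster(matrix(0, 3, 3), pixel_size = 1)
  expect_error(medoid_composite(list(a, b)), "grid")
  expect_identical(medoid_composite(list(a)), a)
})

test_that("histogram matching maps ranks onto the reference distribution", {
  src <- rast(matrix(c(1, 2, 3, 4), 2, 2), ps = 1)
  ref <- rast(matrix(c(10, 20, 30, 40), 2, 2), ps = 1)
  hm <- histogram_match(src, ref)
  expect_close(sort(as.vector(hm$values)), c(10, 20, 30, 40), tol = 1e-6)
  # fixed point and constants
  self <- histogram_match(src, src)
  expect_close(self$values, src$values, tol = 1e-6)
  const <- histogram_match(rast(matrix(5, 3, 3), ps = 1), rast(matrix(7, 3, 3), ps = 1))
  expect_close(const$values, 7, tol = 1e-9)
})

test_that("histogram matching is idempotent and preserves the valid mask", {
  set.seed(2)
  m <- matrix(rnorm(400), 20, 20); m[3, 5] <- NA
  src <- rast(m, ps = 1)
  ref <- rast(matrix(rnorm(400, 5, 2), 20, 20), ps = 1)
  h1 <- histogram_match(src, ref)
  h2 <- histogram_match(h1, ref)
  expect_true(is.na(h1$values[3, 5, 1]))
  # idempotent within the quantile-knot quantization width
  quantization <- diff(range(ref$values)) / 255
  expect_lt(max(abs(h1$values - h2$values), na.rm = TRUE), quantization)
})

test_that("annual composite removes the seam between differently-gained scenes", {
  # two overlapping noiseless renders of one landscape, different gains
  base <- matrix(rep(seq(0.1, 0.5, length.out = 40), each = 20), 20, 40)
  full <- rast(base, ps = 1)
  s1 <- raster_crop(full, 1:20, 1:24); s1$values <- s1$values * 1.2 + 0.05
  s2 <- raster_crop(full, 1:20, 17:40); s2$values <- s2$values * 0.9 - 0.02
  ref <- full
  comp <- build_annual_composite(list(s1, s2), ref)
  expect_equal(dim(comp$values)[1:2], c(20L, 40L))
  expect_true(all(!is.na(comp$values)))   # disjoint + overlap coverage
  # seam statistic: after matching, the cross-seam step stays at the scale of
  # the natural image gradient; without matching it would be dominated by the
  # 1.2 vs 0.9 gain disparity (~0.1 on these values)
  seam_diff <- mean(abs(comp$values[, 20, 1] - comp$values[, 21, 1]))
  grad <- mean(abs(base[, 20] - base[, 21]))
  expect_lt(seam_diff, 3 * grad)
  expect_lt(seam_diff, 0.1)
})

test_that("composite validity mask is the union of scene masks", {
  a <- mb_raster(matrix(c(1, NA, 2, NA), 1, 4), xmin = 0, ymax = 1, pixel_size = 1)
  b <- mb_raster(matrix(c(NA, 5, NA, NA), 1, 4), xmin = 0, ymax = 1, pixel_size = 1)
  ref <- mb_raster(matrix(1:4, 1, 4), xmin = 0, ymax = 1, pixel_size = 1)
  comp <- build_annual_composite(list(a, b), ref)
  expect_equal(is.na(comp$values[1, , 1]), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("stack_elevation appends a DEM band, exact on-grid and ramp-faithful", {
  comp <- mb_raster(array(0, dim = c(10, 10, 4)), pixel_size = 3,
                    bands = c("B", "G", "R", "NIR"))
  dem_exact <- mb_raster(matrix(rnorm(100), 10, 10), pixel_size = 3, bands = "DEM")
  se <- stack_elevation(comp, dem_exact)
  expect_equal(se$bands[5], "DEM")
  expect_identical(se$values[, , 5], dem_exact$values[, , 1])
  # constant DEM resampled stays constant
  demc <- mb_raster(matrix(2.5, 1, 1), pixel_size = 30, bands = "DEM")
  se2 <- stack_elevation(mb_raster(array(0, dim = c(10, 10, 4)), pixel_size = 3), demc)
  expect_close(se2$values[, , 5], 2.5, tol = 1e-9)
})
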