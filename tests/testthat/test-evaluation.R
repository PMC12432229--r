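make_dep_set <- function(mask, ps = 3, xmin = 0) {
  vectorize_and_measure(mask, mb_raster(matrix(0, nrow(mask), ncol(mask)),
                                        xmin = xmin, pixel_size = ps))
}

test_that("grid comparison: identity, proportional and empty-prediction limits", {
  set.seed(31)
  dep <- data.frame(x = runif(40, 0, 5120), y = runif(40, 0, 5120),
                    area_m2 = runif(40, 50, 5000))
  r <- grid_compare(dep, dep)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$relative_bias_percent, 0)
  # proportional prediction: slope 0.8, bias -20, r2 = 1
  pred <- dep; pred$area_m2 <- 0.8 * dep$area_m2
  r2 <- grid_compare(pred, dep)
  expect_equal(r2$slope, 0.8, tolerance = 1e-9)
  expect_equal(r2$r_squared, 1, tolerance = 1e-9)
  expect_equal(r2$relative_bias_percent, -20, tolerance = 1e-9)
  # swapping prediction and reference inverts a proportional slope
  r2b <- grid_compare(dep, pred)
  expect_equal(r2b$slope, 1 / 0.8, tolerance = 1e-9)
  # empty prediction
  r3 <- grid_compare(dep[0, ], dep)
  expect_equal(r3$relative_bias_percent, -100)
  # zero reference flagged
  r4 <- grid_compare(dep, dep[0, ])
  expect_true("zero_reference_area" %in% r4$flags)
})

test_that("size-stratified bias: exact per-bin accounting on constructed fixtures", {
  # reference: one large deposit and one tiny (sub-MMU) deposit
  ref_mask <- matrix(FALSE, 30, 60)
  ref_mask[5:24, 5:24] <- TRUE             # 400 px = 3600 m2 at 3 m
  ref_mask[2, 40] <- TRUE                  # 9 m2, below 100
  ref <- make_dep_set(ref_mask)
  # prediction finds only the large deposit, exactly
  pred_mask <- ref_mask; pred_mask[2, 40] <- FALSE
  pred <- make_dep_set(pred_mask)
  sb <- size_stratified_bias(pred, ref)
  small <- sb[sb$bin == "(0,100]", ]
  mid <- sb[sb$bin == "(100,10000]", ]
  expect_equal(small$bias_percent, -100)
  expect_equal(mid$bias_percent, 0)
  expect_equal(small$ref_coverage, 0)
  expect_equal(mid$ref_coverage, 1)
  expect_equal(attr(sb, "share_below_first_edge"), 9 / 3609)
  # excluding sub-MMU deposits removes the residual bias entirely
  gc <- grid_compare(pred, ref)
  expect_lt(gc$relative_bias_percent, 0)
  expect_equal(gc$relative_bias_excl_small_percent, 0, tolerance = 1e-9)
  # pred-only deposits land in the commission line
  extra_mask <- pred_mask; extra_mask[28, 50:55] <- TRUE
  sb2 <- size_stratified_bias(make_dep_set(extra_mask), ref)
  expect_equal(sb2$pred_area_m2[sb2$bin == "commission"], 6 * 9)
})

test_that("overall bias equals the area-weighted combination of per-bin biases", {
  set.seed(32)
  ref_mask <- matrix(FALSE, 60, 60)
  ref_mask[2:3, 2:3] <- TRUE               # 36 m2 (small bin)
  ref_mask[10:29, 10:29] <- TRUE           # 3600 m2 (middle bin)
  ref_mask[35:57, 35:57] <- TRUE           # 4761 m2 (middle bin)
  ref <- make_dep_set(ref_mask)
  pred_mask <- ref_mask
  pred_mask[2:3, 2:3] <- FALSE             # miss the small one
  pred_mask[10:19, 10:29] <- FALSE         # miss half of one deposit
  pred <- make_dep_set(pred_mask)
  sb <- size_stratified_bias(pred, ref)
  bins <- sb[sb$bin != "commission", ]
  combined <- sum(bins$bias_percent * bins$ref_area_m2, na.rm = TRUE) /
    sum(bins$ref_area_m2)
  gc <- grid_compare(pred, ref)
  expect_equal(gc$relative_bias_percent, combined, tolerance = 1e-9)
})
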