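test_that("Tversky loss reproduces hand-computed soft counts and conventions", {
  # TP=2, FP=1, FN=1, alpha=0.3, beta=0.7, eps -> 0: loss = 1 - 2/3
  pred <- c(1, 1, 1, 0, 0)
  truth <- c(1, 1, 0, 1, 0)
  expect_equal(tversky_loss(pred, truth, 0.3, 0.7, 0), 1 - 2 / 3)
  # perfect prediction and the all-empty epsilon convention
  expect_equal(tversky_loss(truth, truth, 0.3, 0.7, 1e-6), 0)
  expect_equal(tversky_loss(numeric(4), numeric(4), 0.3, 0.7, 1e-6), 0)
  expect_error(tversky_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("Tversky with alpha = beta = 0.5 equals the Dice loss", {
  set.seed(4)
  for (k in 1:5) {
    p <- matrix(runif(64), 8, 8)
    t <- matrix(rbinom(64, 1, 0.4), 8, 8)
    tp <- sum(p * t); fp <- sum(p * (1 - t)); fn <- sum((1 - p) * t)
    dice <- 1 - 2 * tp / (2 * tp + fp + fn)
    expect_equal(tversky_loss(p, t, 0.5, 0.5, 0), dice, tolerance = 1e-12)
  }
})

test_that("Tversky loss decreases as predictions move toward the truth", {
  set.seed(5)
  for (k in 1:5) {
    t <- matrix(rbinom(100, 1, 0.3), 10, 10)
    p <- matrix(runif(100), 10, 10)
    steps <- vapply(seq(0, 1, by = 0.25), function(s)
      tversky_loss(p + s * (t - p), t, 0.3, 0.7, 1e-6), 0)
    expect_true(all(diff(steps) <= 1e-12))
  }
})

test_that("network gradients match finite differences", {
  cfg <- seg_model_config(input_bands = 2, depth = 2, base_filters = 3,
                          patch_size = 8, seed = 3)
  mdl <- build_unet(cfg)
  set.seed(42)
  xs <- list(array(rnorm(128), dim = c(8, 8, 2)), array(rnorm(128), dim = c(8, 8, 2)))
  ys <- list(matrix(rbinom(64, 1, 0.3), 8, 8), matrix(rbinom(64, 1, 0.3), 8, 8))
  fw <- driftmapr:::unet_forward(mdl, xs, training = TRUE)
  pred_all <- array(unlist(fw$preds), dim = c(8, 8, 1, 2))
  truth_all <- array(unlist(ys), dim = c(8, 8, 1, 2))
  dflat <- driftmapr:::tversky_grad(pred_all, truth_all, 0.3, 0.7, 1e-6)
  gr <- driftmapr:::unet_backward(mdl, xs, fw,
                                  lapply(1:2, function(i) array(dflat[, , , i], dim = c(8, 8, 1))))
  numgrad <- function(setter) {
    eps <- 1e-5
    lossat <- function(sgn) {
      m <- mdl; m$params <- setter(mdl$params, sgn * eps)
      f <- driftmapr:::unet_forward(m, xs, training = TRUE)
      tversky_loss(array(unlist(f$preds), dim = dim(pred_all)), truth_all, 0.3, 0.7, 1e-6)
    }
    (lossat(1) - lossat(-1)) / (2 * eps)
  }
  checks <- list(
    list(gr$enc[[1]]$conv1$dW[1, 1], function(p, e) { p$enc[[1]]$conv1$W[1, 1] <- p$enc[[1]]$conv1$W[1, 1] + e; p }),
    list(gr$dec[[1]]$conv1$dW[5, 2], function(p, e) { p$dec[[1]]$conv1$W[5, 2] <- p$dec[[1]]$conv1$W[5, 2] + e; p }),
    list(gr$out$dW[2, 1],            function(p, e) { p$out$W[2, 1] <- p$out$W[2, 1] + e; p }),
    list(gr$enc[[1]]$conv1$dgamma[2], function(p, e) { p$enc[[1]]$bn1$gamma[2] <- p$enc[[1]]$bn1$gamma[2] + e; p }))
  for (chk in checks) {
    nu <- numgrad(chk[[2]])
    expect_equal(chk[[1]], nu, tolerance = 1e-5)
  }
})

test_that("model contract: output shape/range, dilation-invariant parameters, seeds", {
  cfg <- seg_model_config(input_bands = 3, depth = 2, base_filters = 4,
                          patch_size = 16, seed = 8)
  mdl <- build_unet(cfg)
  x <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
  p <- predict(mdl, x)
  expect_equal(dim(p), c(16L, 16L))
  expect_true(all(p >= 0 & p <= 1))
  # dilation changes receptive field, not parameters
  cfg_d1 <- cfg; cfg_d1$dilation_rate <- 1L
  n1 <- build_unet(cfg_d1)$n_params
  expect_equal(n1, mdl$n_params)
  # same seed -> identical initial weights; different seed -> different
  expect_identical(build_unet(cfg)$params$enc[[1]]$conv1$W,
                   mdl$params$enc[[1]]$conv1$W)
  cfg_s9 <- cfg; cfg_s9$seed <- 9L
  expect_false(identical(build_unet(cfg_s9)$params$enc[[1]]$conv1$W,
                         mdl$params$enc[[1]]$conv1$W))
  # indivisible input errors with the required padding
  bad <- array(0, dim = c(15, 16, 3))
  expect_error(predict(mdl, bad), "divisible")
})

test_that("area splitting is deterministic, size-exact and disjoint", {
  sp <- split_areas(1:10, c(0.6, 0.2, 0.2), seed = 4)
  expect_equal(lengths(sp), c(train = 6L, val = 2L, test = 2L))
  expect_setequal(unlist(sp), 1:10)
  expect_identical(sp, split_areas(1:10, c(0.6, 0.2, 0.2), seed = 4))
  expect_equal(split_areas(letters[1:5], c(1, 0, 0), seed = 1)$train |> sort(),
               letters[1:5])
  expect_error(split_areas(1:2, c(0.6, 0.2, 0.2)), "3 areas")
  expect_error(split_areas(1:10, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("patch sampling respects areas, alignment and determinism", {
  comp <- mb_raster(array(seq_len(20 * 30 * 2) / 100, dim = c(20, 30, 2)), pixel_size = 3)
  labels <- matrix(0, 20, 30); labels[5:9, 10:14] <- 1
  expect_length(sample_patches(comp, labels, 0, 8), 0L)
  ps <- sample_patches(comp, labels, 5, 8, seed = 2)
  for (p in ps) {
    r0 <- p$corner["row"]; c0 <- p$corner["col"]
    expect_identical(p$x, comp$values[r0:(r0 + 7), c0:(c0 + 7), , drop = FALSE])
    expect_identical(p$y, (labels[r0:(r0 + 7), c0:(c0 + 7)] > 0) * 1)
  }
  ps2 <- sample_patches(comp, labels, 5, 8, seed = 2)
  expect_identical(lapply(ps, `[[`, "corner"), lapply(ps2, `[[`, "corner"))
  # all-background labels give all-zero masks
  ps0 <- sample_patches(comp, labels * 0, 3, 8, seed = 1)
  expect_true(all(vapply(ps0, function(p) all(p$y == 0), TRUE)))
  expect_error(sample_patches(comp, labels, 1, 64,
                              areas = data.frame(name = "tiny", row0 = 1, col0 = 1,
                                                 row1 = 10, col1 = 10)),
               "tiny")
})

test_that("augmentation: involution, mask contracts and zero-warp identity", {
  set.seed(6)
  pair <- list(x = array(runif(16 * 16 * 2), dim = c(16, 16, 2)),
               y = matrix(rbinom(256, 1, 0.3), 16, 16))
  # flip twice restores the original
  f1 <- augment(pair, "flip_horizontal", seed = 1)[[1]]
  f2 <- augment(f1, "flip_horizontal", seed = 2)[[1]]
  expect_identical(f2$x, pair$x)
  expect_identical(f2$y, pair$y)
  # photometric ops never touch the mask
  for (op in c("gamma_contrast", "linear_contrast", "normalize", "gaussian_blur")) {
    a <- augment(pair, op, seed = 3)[[1]]
    expect_identical(a$y, pair$y)
    expect_false(identical(a$x, pair$x))
  }
  # geometric ops keep image and mask aligned: a blob warps with its mask
  expect_error(augment(pair, "sharpen", seed = 1), "unknown")
  # zero-displacement warp is the identity (bilinear sampling at integers)
  zero <- driftmapr:::warp_pair(pair, matrix(seq_len(16), 16, 16, byrow = TRUE),
                                matrix(seq_len(16), 16, 16))
  expect_equal(zero$x, pair$x, tolerance = 1e-12)
  expect_identical(zero$y, pair$y)
  # determinism
  a1 <- augment(pair, c("perspective", "piecewise_affine"), seed = 9)
  a2 <- augment(pair, c("perspective", "piecewise_affine"), seed = 9)
  expect_identical(a1, a2)
})

test_that("training descends on a separable task and flags degenerate labels", {
  mk <- function(seed) {
    set.seed(seed)
    y <- matrix(0, 16, 16)
    r <- sample(4:12, 1); c <- sample(4:12, 1)
    y[(r - 2):(r + 2), (c - 2):(c + 2)] <- 1
    x <- array(0, dim = c(16, 16, 2))
    x[, , 1] <- 0.3 + 0.02 * rnorm(256)
    x[, , 2] <- 0.2 + 0.3 * y + 0.02 * rnorm(256)
    list(x = x, y = y)
  }
  cfg <- seg_model_config(input_bands = 2, depth = 2, base_filters = 6,
                          patch_size = 16, epochs = 6, batch_size = 6,
                          learning_rate = 0.02, seed = 5)
  fit <- train_unet(build_unet(cfg), lapply(1:12, mk), lapply(101:104, mk),
                    config = cfg)
  expect_gt(fit$history$train_loss[1], min(fit$history$train_loss))
  expect_gt(fit$val_metrics$iou, 0.3)
  # all-background labels: model output collapses, sensitivity undefined
  bg <- lapply(1:6, function(s) { p <- mk(s); p$y[] <- 0; p })
  cfg2 <- cfg; cfg2$epochs <- 2L
  fit0 <- train_unet(build_unet(cfg), bg, bg[1:2], config = cfg2)
  expect_true("sensitivity" %in% fit0$val_metrics$undefined)
})

test_that("tiled prediction: stride arithmetic, union rule, order invariance", {
  # patch grid for a 1000 px row with 2% overlap of a 512 patch
  expect_equal(driftmapr:::patch_origins(1000, 512, 0.02), c(0L, 488L))
  expect_equal(driftmapr:::patch_origins(512, 512, 0.02), 0L)
  # union rule with a hand-built model-free check: constant-zero model
  cfg <- seg_model_config(input_bands = 2, depth = 1, base_filters = 2,
                          patch_size = 16, seed = 1)
  mdl <- build_unet(cfg)
  mdl$params$out$W[] <- 0
  mdl$params$out$b <- -50           # sigmoid -> ~0 everywhere
  comp <- mb_raster(array(rnorm(24 * 40 * 2), dim = c(24, 40, 2)), pixel_size = 3)
  pr <- predict_tiled(mdl, comp, cfg)
  expect_equal(sum(pr$binary$values), 0)
  expect_true(all(pr$probability$values < 1e-6))
  mdl$params$out$b <- 50            # sigmoid -> ~1 everywhere
  pr1 <- predict_tiled(mdl, comp, cfg)
  expect_equal(mean(pr1$binary$values), 1)
})

test_that("confusion metrics match direct counts and flag undefined ratios", {
  # TP=2, FP=1, FN=1, TN=12
  pred <- c(1, 1, 1, 0, rep(0, 12))
  truth <- c(1, 1, 0, 1, rep(0, 12))
  m <- confusion_metrics(pred, truth)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 12 / 13)
  expect_equal(m$accuracy, 14 / 16)
  expect_equal(m$iou, 0.5)
  # IoU <= sensitivity and <= precision
  prec <- 2 / 3
  expect_lte(m$iou, m$sensitivity)
  expect_lte(m$iou, prec)
  perf <- confusion_metrics(truth, truth)
  expect_equal(unlist(perf[c("accuracy", "sensitivity", "specificity", "iou")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, iou = 1))
  und <- confusion_metrics(rep(0, 5), rep(0, 5))
  expect_true(all(c("sensitivity", "iou") %in% und$undefined))
  expect_error(confusion_metrics(1:4, 1:5), "shape")
})
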