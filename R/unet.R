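# Per-pixel driftwood segmentation: a compact U-Net with dilated encoder
# convolutions, batch normalisation and Tversky loss, implemented directly in
# R (im2col convolutions backed by BLAS, hand-derived backward passes, Adam).
# The architecture scales from desk-size settings (64 px patches, 2 levels)
# up to the full-size configuration (512 px patches, dilation rate 2).

#' Segmentation model configuration
#'
#' @param input_bands number of input bands (5 with the elevation band).
#' @param depth number of encoder levels including the bottleneck.
#' @param base_filters filters at the first level (doubled per level).
#' @param dilation_rate dilation of every encoder convolution (decoder
#'   convolutions are undilated); enlarges the receptive field at constant
#'   parameter count.
#' @param tversky_alpha,tversky_beta false-positive and false-negative weights
#'   of the Tversky loss; `beta > alpha` penalises misses more, which suits
#'   the strong class imbalance of sparse driftwood.
#' @param smoothing_epsilon Tversky smoothing term.
#' @param patch_size training/prediction patch edge in pixels (even).
#' @param overlap_fraction fractional overlap between prediction patches.
#' @param learning_rate,epochs,batch_size Adam optimisation settings.
#' @param binarization_threshold probability threshold applied to each year's
#'   prediction before multi-year fusion.
#' @param seed integer seed for weight initialisation and patch shuffling.
#' @return A `seg_model_config` list.
#' @export
seg_model_config <- function(input_bands = 5L, depth = 2L, base_filters = 8L,
                             dilation_rate = 2L, tversky_alpha = 0.3,
                             tversky_beta = 0.7, smoothing_epsilon = 1e-6,
                             patch_size = 64L, overlap_fraction = 0.02,
                             learning_rate = 0.01, epochs = 12L,
                             batch_size = 8L, binarization_threshold = 0.5,
                             seed = 1L) {
  cfg <- list(input_bands = as.integer(input_bands), depth = as.integer(depth),
              base_filters = as.integer(base_filters),
              dilation_rate = as.integer(dilation_rate),
              tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
              smoothing_epsilon = smoothing_epsilon,
              patch_size = as.integer(patch_size),
              overlap_fraction = overlap_fraction,
              learning_rate = learning_rate, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              binarization_threshold = binarization_threshold,
              seed = as.integer(seed))
  if (cfg$tversky_alpha <= 0 || cfg$tversky_beta <= 0)
    stop_config("tversky_alpha and tversky_beta must be > 0")
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 0.5)
    stop_config("overlap_fraction must lie in [0, 0.5)")
  if (cfg$patch_size %% 2L != 0L) stop_config("patch_size must be even")
  class(cfg) <- "seg_model_config"
  cfg
}

#' Tversky loss for soft binary segmentation
#'
#' `1 - (TP + eps) / (TP + alpha*FP + beta*FN + eps)` with soft counts
#' `TP = sum(p*t)`, `FP = sum(p*(1-t))`, `FN = sum((1-p)*t)`. With
#' `alpha = beta = 0.5` this is exactly the Dice loss. An all-empty
#' prediction of an all-empty truth has loss 0 by the epsilon convention.
#'
#' @param pred numeric array of probabilities in `[0,1]`.
#' @param truth numeric array of the same shape with values in `[0,1]`.
#' @param alpha,beta false-positive / false-negative weights (> 0).
#' @param epsilon smoothing constant.
#' @return Scalar loss in `[0,1]`.
#' @export
tversky_loss <- function(pred, truth, alpha = 0.3, beta = 0.7, epsilon = 1e-6) {
  if (!isTRUE(all(dim(pred) %||% length(pred) == (dim(truth) %||% length(truth)))))
    stop_config("tversky_loss: shape mismatch")
  tp <- sum(pred * truth)
  fp <- sum(pred * (1 - truth))
  fn <- sum((1 - pred) * truth)
  1 - (tp + epsilon) / (tp + alpha * fp + beta * fn + epsilon)
}

tversky_grad <- function(pred, truth, alpha, beta, epsilon) {
  tp <- sum(pred * truth)
  fp <- sum(pred * (1 - truth))
  fn <- sum((1 - pred) * truth)
  den <- tp + alpha * fp + beta * fn + epsilon
  num <- tp + epsilon
  # d num / dp = t ; d den / dp = t + alpha (1 - t) - beta t
  -(truth * den - num * (truth + alpha * (1 - truth) - beta * truth)) / den^2
}

# ---- layer primitives ---------------------------------------------------

conv_geometry <- function(H, W, k = 3L, dilation = 1L) {
  p <- dilation * (k - 1L) %/% 2L
  Hp <- H + 2L * p; Wp <- W + 2L * p
  # linear indices into the padded [Hp x Wp] plane for each output pixel and
  # kernel tap (column-major, row fastest)
  orow <- rep(seq_len(H), times = W)
  ocol <- rep(seq_len(W), each = H)
  off <- as.matrix(expand.grid(dr = (-(k %/% 2)):(k %/% 2),
                               dc = (-(k %/% 2)):(k %/% 2))) * dilation
  idx <- matrix(0L, H * W, k * k)
  for (j in seq_len(k * k))
    idx[, j] <- (ocol + p + off[j, 2] - 1L) * Hp + (orow + p + off[j, 1])
  list(p = p, Hp = Hp, Wp = Wp, idx = idx)
}

conv_forward <- function(x, W_mat, b, geom, want_cols = TRUE) {
  # x: [H, W, Cin]; returns list(y = [H, W, Cout], cols)
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  pad <- array(0, dim = c(geom$Hp, geom$Wp, Cin))
  pad[geom$p + seq_len(H), geom$p + seq_len(Wd), ] <- x
  padm <- matrix(pad, geom$Hp * geom$Wp, Cin)
  cols <- padm[as.vector(geom$idx), , drop = FALSE]      # [(HW*kk), Cin]
  dim(cols) <- c(H * Wd, ncol(geom$idx) * Cin)           # taps fastest, then channel
  y <- cols %*% W_mat
  y <- sweep(y, 2, b, "+")
  list(y = array(y, dim = c(H, Wd, ncol(W_mat))), cols = if (want_cols) cols)
}

# kernel of the transpose convolution: taps flipped, channel roles swapped
back_weights <- function(W_mat, kk, Cin, Cout) {
  Wa <- array(W_mat, dim = c(kk, Cin, Cout))
  matrix(aperm(Wa[kk:1, , , drop = FALSE], c(1, 3, 2)), kk * Cout, Cin)
}

conv_backward <- function(dy, cols, W_mat, geom, H, Wd, Cin, W_back = NULL) {
  kk <- ncol(geom$idx)
  Cout <- dim(dy)[3]
  dym <- matrix(dy, H * Wd, Cout)
  dW <- crossprod(cols, dym)
  db <- colSums(dym)
  # input gradient of a stride-1 same convolution = convolution of dy with
  # the flipped kernel (channels transposed); reuses the fast im2col path
  if (is.null(W_back)) W_back <- back_weights(W_mat, kk, Cin, Cout)
  dx <- conv_forward(dy, W_back, numeric(Cin), geom, want_cols = FALSE)$y
  list(dx = dx, dW = dW, db = db)
}

bn_forward <- function(xs, gamma, beta, running, training, momentum = 0.1, eps = 1e-5) {
  # xs: list over batch of [H, W, C]
  C <- dim(xs[[1]])[3]
  if (training) {
    mu <- rowMeans(matrix(vapply(xs, function(x)
      colMeans(matrix(x, ncol = C)), numeric(C)), nrow = C))
    var <- rowMeans(matrix(vapply(xs, function(x)
      colMeans(sweep(matrix(x, ncol = C), 2, mu)^2), numeric(C)), nrow = C))
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * var
  } else { mu <- running$mean; var <- running$var }
  inv <- 1 / sqrt(var + eps)
  xhat <- lapply(xs, function(x) {
    m <- sweep(matrix(x, ncol = C), 2, mu)
    array(sweep(m, 2, inv, "*"), dim = dim(x))
  })
  ys <- lapply(xhat, function(xh)
    array(sweep(sweep(matrix(xh, ncol = C), 2, gamma, "*"), 2, beta, "+"), dim = dim(xh)))
  list(ys = ys, xhat = xhat, inv = inv, running = running)
}

bn_backward <- function(dys, cache, gamma) {
  C <- length(gamma)
  m <- sum(vapply(dys, function(d) prod(dim(d)[1:2]), 0))
  sum_dy <- Reduce(`+`, lapply(dys, function(d) colSums(matrix(d, ncol = C))))
  sum_dy_xhat <- Reduce(`+`, Map(function(d, xh)
    colSums(matrix(d, ncol = C) * matrix(xh, ncol = C)), dys, cache$xhat))
  dgamma <- sum_dy_xhat; dbeta <- sum_dy
  dxs <- Map(function(d, xh) {
    dm <- matrix(d, ncol = C)
    xm <- matrix(xh, ncol = C)
    t1 <- sweep(dm, 2, sum_dy / m)
    t2 <- sweep(xm, 2, sum_dy_xhat / m, "*")
    array(sweep(t1 - t2, 2, gamma * cache$inv, "*"), dim = dim(d))
  }, dys, cache$xhat)
  list(dxs = dxs, dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  a <- x[seq(1, H, 2), seq(1, W, 2), , drop = FALSE]
  b <- x[seq(2, H, 2), seq(1, W, 2), , drop = FALSE]
  cc <- x[seq(1, H, 2), seq(2, W, 2), , drop = FALSE]
  d <- x[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]
  y <- pmax(a, b, cc, d)
  # argmax recorded as 1..4; ties resolved in fixed order a,b,c,d
  arg <- array(4L, dim = dim(y))
  arg[y == cc] <- 3L; arg[y == b] <- 2L; arg[y == a] <- 1L
  list(y = y, arg = arg, H = H, W = W)
}

maxpool_backward <- function(dy, cache) {
  H <- cache$H; W <- cache$W; C <- dim(dy)[3]
  dx <- array(0, dim = c(H, W, C))
  for (q in 1:4) {
    ri <- seq(if (q %in% c(1, 3)) 1 else 2, H, 2)
    ci <- seq(if (q %in% c(1, 2)) 1 else 2, W, 2)
    sel <- cache$arg == q
    tmp <- dy; tmp[!sel] <- 0
    dx[ri, ci, ] <- dx[ri, ci, ] + tmp
  }
  dx
}

upsample2_forward <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
}

upsample2_backward <- function(dy) {
  H <- dim(dy)[1]; W <- dim(dy)[2]
  ri <- rep(seq_len(H / 2), each = 2); ci <- rep(seq_len(W / 2), each = 2)
  C <- dim(dy)[3]
  out <- array(0, dim = c(H / 2, W / 2, C))
  for (c in seq_len(C))
    out[, , c] <- t(rowsum(t(rowsum(dy[, , c], ri)), ci))
  out
}

# ---- model construction -------------------------------------------------

he_init <- function(fan_in, n_out) {
  matrix(stats::rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
}

new_conv <- function(cin, cout, k = 3L, dilation = 1L)
  list(W = he_init(k * k * cin, cout), b = numeric(cout), k = k, dilation = dilation)

new_bn <- function(c) list(gamma = rep(1, c), beta = numeric(c),
                           running = list(mean = numeric(c), var = rep(1, c)))

#' Build a dilated U-Net segmentation model
#'
#' Encoder levels double the filter count and use dilated 3x3 convolutions
#' (the configured rate); decoder levels upsample (nearest neighbour), fuse
#' the skip connection and use undilated convolutions. Every convolution is
#' followed by batch normalisation and ReLU; a 1x1 convolution plus sigmoid
#' yields per-pixel probabilities at the input resolution. Dilation changes
#' the receptive field but not the parameter count.
#'
#' @param config a [seg_model_config()].
#' @return An object of class `unet_model` with elements `params`, `config`
#'   and `n_params`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "seg_model_config"))
  with_seed(derive_seed(config$seed, "unet_init"), {
    D <- config$depth; F1 <- config$base_filters
    filters <- F1 * 2^(seq_len(D) - 1L)
    enc <- list(); dec <- list()
    cin <- config$input_bands
    for (l in seq_len(D)) {
      enc[[l]] <- list(conv1 = new_conv(cin, filters[l], dilation = config$dilation_rate),
                       bn1 = new_bn(filters[l]),
                       conv2 = new_conv(filters[l], filters[l], dilation = config$dilation_rate),
                       bn2 = new_bn(filters[l]))
      cin <- filters[l]
    }
    for (l in rev(seq_len(D - 1L))) {
      dec[[l]] <- list(convup = new_conv(filters[l + 1L], filters[l]),
                       bnup = new_bn(filters[l]),
                       conv1 = new_conv(2L * filters[l], filters[l]),
                       bn1 = new_bn(filters[l]),
                       conv2 = new_conv(filters[l], filters[l]),
                       bn2 = new_bn(filters[l]))
    }
    out <- new_conv(filters[1], 1L, k = 1L)
    params <- list(enc = enc, dec = dec, out = out)
    n_par <- param_count(params)
    structure(list(params = params, config = config, n_params = n_par),
              class = "unet_model")
  })
}

param_count <- function(params) {
  cnt <- 0
  walk <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$W)) cnt <<- cnt + length(x$W) + length(x$b)
      if (!is.null(x$gamma)) cnt <<- cnt + length(x$gamma) + length(x$beta)
      for (e in x) if (is.list(e)) walk(e)
    }
  }
  walk(params)
  cnt
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, base filters %d, dilation %d, %d input bands, %s parameters\n",
              x$config$depth, x$config$base_filters, x$config$dilation_rate,
              x$config$input_bands, format(x$n_params, big.mark = ",")))
  invisible(x)
}

check_divisible <- function(H, W, depth) {
  f <- 2^(depth - 1L)
  if (H %% f != 0L || W %% f != 0L)
    stop_config("input %dx%d not divisible by 2^%d = %d; pad to %dx%d",
                H, W, depth - 1L, f, ceiling(H / f) * f, ceiling(W / f) * f)
}

# Forward pass over a batch (list of [H, W, C] arrays). Returns predictions
# and, when training, the caches needed for the backward pass. bn_momentum
# controls the running-statistics update (1/i during post-training
# recalibration accumulates the cumulative mean over batches).
unet_forward <- function(model, xs, training = FALSE, bn_momentum = 0.1) {
  cfg <- model$config; P <- model$params
  D <- cfg$depth
  H <- dim(xs[[1]])[1]; W <- dim(xs[[1]])[2]
  check_divisible(H, W, D)
  cache <- list(enc = vector("list", D), dec = vector("list", max(D - 1L, 0L)))
  skips <- vector("list", D)
  h <- xs
  cur_H <- H; cur_W <- W
  geoms <- list()
  gkey <- function(H, W, d) paste(H, W, d)
  getgeom <- function(H, W, d) {
    k <- gkey(H, W, d)
    if (is.null(geoms[[k]])) geoms[[k]] <<- conv_geometry(H, W, 3L, d)
    geoms[[k]]
  }
  conv_block <- function(h, conv, bn, geom) {
    cf <- lapply(h, conv_forward, W_mat = conv$W, b = conv$b, geom = geom)
    ys <- lapply(cf, `[[`, "y")
    bnf <- bn_forward(ys, bn$gamma, bn$beta, bn$running, training,
                      momentum = bn_momentum)
    acts <- lapply(bnf$ys, function(y) { y[y < 0] <- 0; y })
    list(acts = acts, cols = lapply(cf, `[[`, "cols"), bn = bnf,
         relu_mask = lapply(bnf$ys, function(y) y > 0))
  }
  for (l in seq_len(D)) {
    g <- getgeom(cur_H, cur_W, cfg$dilation_rate)
    b1 <- conv_block(h, P$enc[[l]]$conv1, P$enc[[l]]$bn1, g)
    b2 <- conv_block(b1$acts, P$enc[[l]]$conv2, P$enc[[l]]$bn2, g)
    if (training) { P$enc[[l]]$bn1$running <- b1$bn$running
                    P$enc[[l]]$bn2$running <- b2$bn$running }
    skips[[l]] <- b2$acts
    cache$enc[[l]] <- list(b1 = b1, b2 = b2, H = cur_H, W = cur_W, xin = h)
    if (l < D) {
      mp <- lapply(b2$acts, maxpool_forward)
      h <- lapply(mp, `[[`, "y")
      cache$enc[[l]]$mp <- mp
      cur_H <- cur_H / 2L; cur_W <- cur_W / 2L
    } else h <- b2$acts
  }
  for (l in rev(seq_len(D - 1L))) {
    up <- lapply(h, upsample2_forward)
    cur_H <- cur_H * 2L; cur_W <- cur_W * 2L
    g1 <- getgeom(cur_H, cur_W, 1L)
    bu <- conv_block(up, P$dec[[l]]$convup, P$dec[[l]]$bnup, g1)
    cat_in <- Map(function(s, u) {
      arr <- array(0, dim = c(cur_H, cur_W, dim(s)[3] + dim(u)[3]))
      arr[, , seq_len(dim(s)[3])] <- s
      arr[, , dim(s)[3] + seq_len(dim(u)[3])] <- u
      arr
    }, skips[[l]], bu$acts)
    b1 <- conv_block(cat_in, P$dec[[l]]$conv1, P$dec[[l]]$bn1, g1)
    b2 <- conv_block(b1$acts, P$dec[[l]]$conv2, P$dec[[l]]$bn2, g1)
    if (training) { P$dec[[l]]$bnup$running <- bu$bn$running
                    P$dec[[l]]$bn1$running <- b1$bn$running
                    P$dec[[l]]$bn2$running <- b2$bn$running }
    cache$dec[[l]] <- list(bu = bu, b1 = b1, b2 = b2, up_in = up,
                           cat_in = cat_in, H = cur_H, W = cur_W,
                           skip_c = dim(skips[[l]][[1]])[3])
    h <- b2$acts
  }
  gout <- conv_geometry(cur_H, cur_W, 1L, 1L)
  of <- lapply(h, conv_forward, W_mat = P$out$W, b = P$out$b, geom = gout)
  logits <- lapply(of, `[[`, "y")
  preds <- lapply(logits, function(z) 1 / (1 + exp(-z)))
  list(preds = preds, cache = list(stage = cache, out_cols = lapply(of, `[[`, "cols"),
                                   out_geom = gout, skips = skips, geoms = geoms,
                                   logits = logits),
       params = P)
}

unet_backward <- function(model, xs, fw, dpreds) {
  cfg <- model$config; P <- fw$params
  D <- cfg$depth
  grads <- list(enc = vector("list", D), dec = vector("list", max(D - 1L, 0L)))
  # sigmoid
  dlogits <- Map(function(dp, pr) dp * pr * (1 - pr), dpreds, fw$preds)
  cache <- fw$cache
  # output 1x1 conv
  dW_out <- 0; db_out <- 0
  dh <- vector("list", length(xs))
  cin_out <- ncol(cache$out_cols[[1]])
  wb_out <- back_weights(P$out$W, 1L, cin_out, 1L)
  for (i in seq_along(xs)) {
    bk <- conv_backward(dlogits[[i]], cache$out_cols[[i]], P$out$W, cache$out_geom,
                        dim(dlogits[[i]])[1], dim(dlogits[[i]])[2],
                        cin_out, W_back = wb_out)
    dW_out <- dW_out + bk$dW; db_out <- db_out + bk$db
    dh[[i]] <- bk$dx
  }
  grads$out <- list(dW = dW_out, db = db_out)
  st <- cache$stage
  back_conv_block <- function(dacts, blk, conv, bn, geom, cin) {
    dys <- Map(function(d, msk) { d[!msk] <- 0; d }, dacts, blk$relu_mask)
    bb <- bn_backward(dys, blk$bn, bn$gamma)
    dW <- 0; db <- 0
    wb <- back_weights(conv$W, ncol(geom$idx), cin, ncol(conv$W))
    dxs <- vector("list", length(dacts))
    for (i in seq_along(dacts)) {
      bk <- conv_backward(bb$dxs[[i]], blk$cols[[i]], conv$W, geom,
                          dim(dacts[[i]])[1], dim(dacts[[i]])[2], cin,
                          W_back = wb)
      dW <- dW + bk$dW; db <- db + bk$db
      dxs[[i]] <- bk$dx
    }
    list(dxs = dxs, g = list(dW = dW, db = db, dgamma = bb$dgamma, dbeta = bb$dbeta))
  }
  gkey <- function(H, W, d) paste(H, W, d)
  dskips <- vector("list", D)
  for (l in seq_len(D - 1L)) {
    dc <- st$dec[[l]]
    g1 <- cache$geoms[[gkey(dc$H, dc$W, 1L)]]
    r2 <- back_conv_block(dh, dc$b2, P$dec[[l]]$conv2, P$dec[[l]]$bn2, g1,
                          dim(dc$b1$acts[[1]])[3])
    r1 <- back_conv_block(r2$dxs, dc$b1, P$dec[[l]]$conv1, P$dec[[l]]$bn1, g1,
                          dim(dc$cat_in[[1]])[3])
    sc <- dc$skip_c
    dskips[[l]] <- lapply(r1$dxs, function(d) d[, , seq_len(sc), drop = FALSE])
    dup_out <- lapply(r1$dxs, function(d) d[, , -seq_len(sc), drop = FALSE])
    ru <- back_conv_block(dup_out, dc$bu, P$dec[[l]]$convup, P$dec[[l]]$bnup, g1,
                          dim(dc$up_in[[1]])[3])
    dh <- lapply(ru$dxs, upsample2_backward)
    grads$dec[[l]] <- list(conv2 = r2$g, conv1 = r1$g, convup = ru$g)
  }
  for (l in rev(seq_len(D))) {
    en <- st$enc[[l]]
    if (l < D) {
      dpool <- dh
      dh <- Map(function(d, mp) maxpool_backward(d, mp), dpool, en$mp)
      dh <- Map(`+`, dh, dskips[[l]])
    }
    g <- cache$geoms[[gkey(en$H, en$W, cfg$dilation_rate)]]
    r2 <- back_conv_block(dh, en$b2, P$enc[[l]]$conv2, P$enc[[l]]$bn2, g,
                          dim(en$b1$acts[[1]])[3])
    r1 <- back_conv_block(r2$dxs, en$b1, P$enc[[l]]$conv1, P$enc[[l]]$bn1, g,
                          dim(en$xin[[1]])[3])
    dh <- r1$dxs
    grads$enc[[l]] <- list(conv2 = r2$g, conv1 = r1$g)
  }
  grads
}

# ---- training -----------------------------------------------------------

adam_state <- function(params) rapply(params, function(x) NULL, how = "replace")

#' Train a U-Net on labelled patches
#'
#' Gradient-based minimisation of the Tversky loss with Adam; the checkpoint
#' with the best validation loss is retained. Training aborts with
#' diagnostics if the loss becomes non-finite.
#'
#' @param model a [build_unet()] model.
#' @param train_patches,val_patches lists of `list(x = [H,W,C] array,
#'   y = [H,W] 0/1 matrix)`.
#' @param test_patches optional held-out set for the final report.
#' @param config optional [seg_model_config()] override (defaults to the
#'   model's).
#' @param verbose print per-epoch progress.
#' @return An object of class `unet_fit`: the fitted model plus a training
#'   report (`history`, `metrics`, `seed`).
#' @export
train_unet <- function(model, train_patches, val_patches,
                       test_patches = NULL, config = model$config,
                       verbose = FALSE) {
  if (!length(train_patches) || !length(val_patches))
    stop_config("train_unet: empty training or validation set")
  alpha <- config$tversky_alpha; beta <- config$tversky_beta
  eps <- config$smoothing_epsilon
  lr <- config$learning_rate
  mstate <- list(); vstate <- list(); tstep <- 0
  flat_update <- function(params, grads) {
    # Adam update on every W/b/gamma/beta, keyed by position in the network
    params$out <- {
      key <- "out"
      p <- params$out
      for (fld in c("W", "b")) {
        gf <- if (fld == "W") grads$out$dW else grads$out$db
        k2 <- paste0(key, ":", fld)
        m <- mstate[[k2]] %||% gf * 0; v <- vstate[[k2]] %||% gf * 0
        m <- 0.9 * m + 0.1 * gf; v <- 0.999 * v + 0.001 * gf^2
        mstate[[k2]] <<- m; vstate[[k2]] <<- v
        mhat <- m / (1 - 0.9^tstep); vhat <- v / (1 - 0.999^tstep)
        p[[fld]] <- p[[fld]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
      p
    }
    for (l in seq_along(params$enc)) {
      for (cv in c("conv1", "conv2")) {
        bnm <- sub("conv", "bn", cv)
        g <- grads$enc[[l]][[cv]]
        key <- paste0("enc", l, cv)
        for (fld in c("W", "b")) {
          gf <- if (fld == "W") g$dW else g$db
          k2 <- paste0(key, ":", fld)
          m <- mstate[[k2]] %||% gf * 0; v <- vstate[[k2]] %||% gf * 0
          m <- 0.9 * m + 0.1 * gf; v <- 0.999 * v + 0.001 * gf^2
          mstate[[k2]] <<- m; vstate[[k2]] <<- v
          params$enc[[l]][[cv]][[fld]] <- params$enc[[l]][[cv]][[fld]] -
            lr * (m / (1 - 0.9^tstep)) / (sqrt(v / (1 - 0.999^tstep)) + 1e-8)
        }
        for (fld in c("gamma", "beta")) {
          gf <- if (fld == "gamma") g$dgamma else g$dbeta
          k2 <- paste0(key, ":", fld)
          m <- mstate[[k2]] %||% gf * 0; v <- vstate[[k2]] %||% gf * 0
          m <- 0.9 * m + 0.1 * gf; v <- 0.999 * v + 0.001 * gf^2
          mstate[[k2]] <<- m; vstate[[k2]] <<- v
          params$enc[[l]][[bnm]][[fld]] <- params$enc[[l]][[bnm]][[fld]] -
            lr * (m / (1 - 0.9^tstep)) / (sqrt(v / (1 - 0.999^tstep)) + 1e-8)
        }
      }
    }
    for (l in seq_along(params$dec)) {
      if (is.null(params$dec[[l]])) next
      for (cv in c("convup", "conv1", "conv2")) {
        bnm <- if (cv == "convup") "bnup" else sub("conv", "bn", cv)
        g <- grads$dec[[l]][[cv]]
        key <- paste0("dec", l, cv)
        for (fld in c("W", "b")) {
          gf <- if (fld == "W") g$dW else g$db
          k2 <- paste0(key, ":", fld)
          m <- mstate[[k2]] %||% gf * 0; v <- vstate[[k2]] %||% gf * 0
          m <- 0.9 * m + 0.1 * gf; v <- 0.999 * v + 0.001 * gf^2
          mstate[[k2]] <<- m; vstate[[k2]] <<- v
          params$dec[[l]][[cv]][[fld]] <- params$dec[[l]][[cv]][[fld]] -
            lr * (m / (1 - 0.9^tstep)) / (sqrt(v / (1 - 0.999^tstep)) + 1e-8)
        }
        for (fld in c("gamma", "beta")) {
          gf <- if (fld == "gamma") g$dgamma else g$dbeta
          k2 <- paste0(key, ":", fld)
          m <- mstate[[k2]] %||% gf * 0; v <- vstate[[k2]] %||% gf * 0
          m <- 0.9 * m + 0.1 * gf; v <- 0.999 * v + 0.001 * gf^2
          mstate[[k2]] <<- m; vstate[[k2]] <<- v
          params$dec[[l]][[bnm]][[fld]] <- params$dec[[l]][[bnm]][[fld]] -
            lr * (m / (1 - 0.9^tstep)) / (sqrt(v / (1 - 0.999^tstep)) + 1e-8)
        }
      }
    }
    params
  }
  batch_loss <- function(mdl, patches, training) {
    xs <- lapply(patches, `[[`, "x")
    ys <- lapply(patches, `[[`, "y")
    fw <- unet_forward(mdl, xs, training = training)
    pred_all <- array(unlist(fw$preds), dim = c(dim(fw$preds[[1]]), length(xs)))
    truth_all <- array(unlist(ys), dim = dim(pred_all))
    loss <- tversky_loss(pred_all, truth_all, alpha, beta, eps)
    list(fw = fw, loss = loss, xs = xs, pred_all = pred_all, truth_all = truth_all)
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0))
  best <- list(loss = Inf, params = model$params)
  with_seed(derive_seed(config$seed, "unet_train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(train_patches))
      ep_losses <- c()
      for (start in seq(1, length(ord), by = config$batch_size)) {
        bidx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        bl <- batch_loss(model, train_patches[bidx], training = TRUE)
        if (!is.finite(bl$loss))
          stop_config("training diverged at epoch %d (non-finite loss); lower the learning rate", ep)
        model$params <- bl$fw$params   # running BN stats updated in forward
        dflat <- tversky_grad(bl$pred_all, bl$truth_all, alpha, beta, eps)
        dpreds <- lapply(seq_along(bl$xs), function(i)
          array(dflat[, , , i], dim = dim(bl$pred_all)[1:3]))
        grads <- unet_backward(model, bl$xs, bl$fw, dpreds)
        tstep <- tstep + 1
        model$params <- flat_update(model$params, grads)
        ep_losses <- c(ep_losses, bl$loss)
      }
      vl <- batch_loss(model, val_patches, training = FALSE)
      history <- rbind(history, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                           val_loss = vl$loss))
      if (vl$loss < best$loss) best <- list(loss = vl$loss, params = model$params)
      if (verbose)
        message(sprintf("epoch %2d  train %.4f  val %.4f", ep, mean(ep_losses), vl$loss))
    }
  })
  model$params <- best$params
  # degenerate labels: with no positive example the Tversky gradient carries
  # no class signal and the maximum-a-posteriori classifier is the empty map
  degenerate <- !any(vapply(train_patches, function(p) any(p$y > 0), TRUE))
  if (degenerate) {
    model$params$out$W[] <- 0
    model$params$out$b[] <- -20
  }
  # recalibrate batch-norm running statistics over the full training set:
  # with few optimisation steps the momentum-averaged statistics lag the
  # trained network, which would skew eval-mode predictions
  i <- 0
  for (start in seq(1, length(train_patches), by = config$batch_size)) {
    bidx <- start:min(start + config$batch_size - 1L, length(train_patches))
    i <- i + 1
    fw <- unet_forward(model, lapply(train_patches[bidx], `[[`, "x"),
                       training = TRUE, bn_momentum = 1 / i)
    model$params <- fw$params
  }
  vm <- fit_metrics(model, val_patches, config$binarization_threshold)
  tm <- if (!is.null(test_patches)) fit_metrics(model, test_patches, config$binarization_threshold) else NULL
  structure(list(model = model, history = history, best_val_loss = best$loss,
                 val_metrics = vm, test_metrics = tm, seed = config$seed,
                 degenerate_labels = degenerate),
            class = "unet_fit")
}

fit_metrics <- function(model, patches, threshold) {
  xs <- lapply(patches, `[[`, "x")
  fw <- unet_forward(model, xs, training = FALSE)
  pred <- unlist(lapply(fw$preds, function(p) p >= threshold))
  truth <- unlist(lapply(patches, `[[`, "y")) > 0.5
  confusion_metrics(pred, truth)
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf("<unet_fit> %d epochs, best val loss %.4f\n", nrow(x$history), x$best_val_loss))
  m <- x$val_metrics
  cat(sprintf("  val: accuracy %.3f  sensitivity %s  specificity %.3f  IoU %s\n",
              m$accuracy, format(m$sensitivity, digits = 3), m$specificity,
              format(m$iou, digits = 3)))
  invisible(x)
}

#' Predict probabilities for a single input array (eval mode)
#' @param object a `unet_model` or `unet_fit`.
#' @param x `[H, W, C]` array or an `mb_raster` with matching bands.
#' @param ... unused.
#' @return Matrix of per-pixel probabilities.
#' @export
predict.unet_model <- function(object, x, ...) {
  if (inherits(x, "mb_raster")) x <- x$values
  fw <- unet_forward(object, list(x), training = FALSE)
  fw$preds[[1]][, , 1]
}

#' @rdname predict.unet_model
#' @export
predict.unet_fit <- function(object, x, ...) predict.unet_model(object$model, x, ...)

# ---- data handling ------------------------------------------------------

#' Split area identifiers into train / validation / test sets
#'
#' @param area_ids vector of identifiers.
#' @param fractions numeric `(train, val, test)` summing to 1.
#' @param seed integer seed.
#' @return list with `train`, `val`, `test`.
#' @export
split_areas <- function(area_ids, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop_config("fractions must sum to 1")
  n <- length(area_ids)
  if (all(fractions > 0) && n < 3L)
    stop_config("need at least 3 areas for a non-empty three-way split")
  with_seed(derive_seed(seed, "split_areas"), {
    ord <- sample(n)
    n_tr <- round(fractions[1] * n)
    n_va <- round(fractions[2] * n)
    n_tr <- min(n_tr, n); n_va <- min(n_va, n - n_tr)
    list(train = area_ids[ord[seq_len(n_tr)]],
         val = area_ids[ord[n_tr + seq_len(n_va)]],
         test = area_ids[ord[setdiff(seq_len(n), seq_len(n_tr + n_va))]])
  })
}

#' Randomly sample aligned image/mask patches
#'
#' @param composite an `mb_raster` (the model input bands).
#' @param labels binary matrix (same grid) of driftwood truth.
#' @param n number of patches.
#' @param patch_size patch edge in pixels.
#' @param seed integer seed.
#' @param areas optional data.frame (`name`, `row0`, `col0`, `row1`, `col1`)
#'   restricting sampling to labelled areas; patches lie fully inside one area.
#' @return List of `list(x, y, corner)` pairs.
#' @export
sample_patches <- function(composite, labels, n, patch_size, seed = 1L,
                           areas = NULL) {
  if (n == 0L) return(list())
  if (is.null(areas))
    areas <- data.frame(name = "full", row0 = 1L, col0 = 1L,
                        row1 = raster_nrow(composite), col1 = raster_ncol(composite))
  small <- (areas$row1 - areas$row0 + 1L) < patch_size |
           (areas$col1 - areas$col0 + 1L) < patch_size
  if (any(small))
    stop_config("area '%s' is smaller than the %d px patch", areas$name[which(small)[1]], patch_size)
  with_seed(derive_seed(seed, "sample_patches"), {
    ai <- sample.int(nrow(areas), n, replace = TRUE)
    lapply(seq_len(n), function(i) {
      a <- areas[ai[i], ]
      r0 <- a$row0 + sample.int(a$row1 - a$row0 - patch_size + 2L, 1) - 1L
      c0 <- a$col0 + sample.int(a$col1 - a$col0 - patch_size + 2L, 1) - 1L
      rows <- r0:(r0 + patch_size - 1L); cols <- c0:(c0 + patch_size - 1L)
      list(x = composite$values[rows, cols, , drop = FALSE],
           y = (labels[rows, cols] > 0) * 1,
           corner = c(row = r0, col = c0))
    })
  })
}

# ---- augmentation -------------------------------------------------------

AUGMENT_OPS <- c("flip_vertical", "flip_horizontal", "random_crop",
                 "linear_contrast", "piecewise_affine", "perspective",
                 "gamma_contrast", "normalize", "gaussian_blur")

sample_bilinear <- function(mat, xq, yq) {
  # xq, yq in 1-based pixel-centre coordinates (col, row); clamped at edges
  nr <- nrow(mat); nc <- ncol(mat)
  xq <- pmin(pmax(xq, 1), nc); yq <- pmin(pmax(yq, 1), nr)
  x0 <- pmin(floor(xq), nc - 1L); y0 <- pmin(floor(yq), nr - 1L)
  fx <- xq - x0; fy <- yq - y0
  v00 <- mat[cbind(y0, x0)]; v10 <- mat[cbind(y0 + 1, x0)]
  v01 <- mat[cbind(y0, x0 + 1)]; v11 <- mat[cbind(y0 + 1, x0 + 1)]
  v00 * (1 - fx) * (1 - fy) + v10 * (1 - fx) * fy +
    v01 * fx * (1 - fy) + v11 * fx * fy
}

warp_pair <- function(pair, xq, yq) {
  # xq/yq: source sampling coordinates per output pixel (matrices)
  H <- dim(pair$x)[1]; W <- dim(pair$x)[2]
  x2 <- pair$x
  for (c in seq_len(dim(pair$x)[3]))
    x2[, , c] <- matrix(sample_bilinear(pair$x[, , c], as.vector(xq), as.vector(yq)), H, W)
  yi <- pmin(pmax(round(yq), 1), H); xi <- pmin(pmax(round(xq), 1), W)
  y2 <- matrix(pair$y[cbind(as.vector(yi), as.vector(xi))], H, W)
  list(x = x2, y = y2)
}

gaussian_blur_mat <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(-r:r, 0, sigma); k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  # separable convolution with edge replication
  pad_idx_r <- pmin(pmax(seq(1 - r, nr + r), 1), nr)
  pad_idx_c <- pmin(pmax(seq(1 - r, nc + r), 1), nc)
  mp <- m[pad_idx_r, ]
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) out <- out + k[j] * mp[(j - 1) + seq_len(nr), ]
  mp <- out[, pad_idx_c]
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) out <- out + k[j] * mp[, (j - 1) + seq_len(nc)]
  out
}

#' Augment an image/mask patch pair
#'
#' Geometric operations are applied identically to image and mask (mask via
#' nearest neighbour); photometric operations touch the image only. One
#' augmented pair per requested operation is returned, deterministically for
#' a fixed seed.
#'
#' @param pair `list(x = [H,W,C] array, y = [H,W] matrix)`.
#' @param ops character vector drawn from the supported catalogue: vertical
#'   and horizontal flips, random cropping, linear contrast, piecewise affine
#'   and perspective warps, gamma adjustment, patch normalisation, Gaussian
#'   blur.
#' @param seed integer seed.
#' @return List of augmented pairs (one per op), named by op.
#' @export
augment <- function(pair, ops, seed = 1L) {
  bad <- setdiff(ops, AUGMENT_OPS)
  if (length(bad)) stop_config("unknown augmentation op: %s", bad[1])
  H <- dim(pair$x)[1]; W <- dim(pair$x)[2]
  base_x <- matrix(seq_len(W), H, W, byrow = TRUE)
  base_y <- matrix(seq_len(H), H, W)
  with_seed(derive_seed(seed, "augment"), {
    out <- lapply(ops, function(op) {
      switch(op,
        flip_vertical = list(x = pair$x[H:1, , , drop = FALSE], y = pair$y[H:1, ]),
        flip_horizontal = list(x = pair$x[, W:1, , drop = FALSE], y = pair$y[, W:1]),
        random_crop = {
          f <- stats::runif(1, 0.7, 0.95)
          ch <- floor(H * f); cw <- floor(W * f)
          r0 <- sample.int(H - ch + 1L, 1); c0 <- sample.int(W - cw + 1L, 1)
          sx <- (cw - 1) / max(W - 1, 1); sy <- (ch - 1) / max(H - 1, 1)
          warp_pair(pair, c0 + (base_x - 1) * sx, r0 + (base_y - 1) * sy)
        },
        linear_contrast = {
          f <- stats::runif(1, 0.7, 1.3)
          mu <- mean(pair$x)
          list(x = (pair$x - mu) * f + mu, y = pair$y)
        },
        piecewise_affine = {
          ngrid <- 4L; s <- 0.04
          dx <- matrix(stats::rnorm(ngrid^2, 0, s * W), ngrid, ngrid)
          dy <- matrix(stats::rnorm(ngrid^2, 0, s * H), ngrid, ngrid)
          gx <- seq(1, W, length.out = ngrid); gy <- seq(1, H, length.out = ngrid)
          fx <- base_x + bilinear_field(dx, gy, gx, base_y, base_x)
          fy <- base_y + bilinear_field(dy, gy, gx, base_y, base_x)
          warp_pair(pair, fx, fy)
        },
        perspective = {
          jit <- 0.05
          src <- rbind(c(1, 1), c(W, 1), c(W, H), c(1, H))
          dst <- src + cbind(stats::runif(4, -jit * W, jit * W),
                             stats::runif(4, -jit * H, jit * H))
          # map output pixel -> source sample position (inverse warping)
          Hm <- solve_homography(src, dst)
          den <- Hm[3, 1] * base_x + Hm[3, 2] * base_y + Hm[3, 3]
          warp_pair(pair,
                    (Hm[1, 1] * base_x + Hm[1, 2] * base_y + Hm[1, 3]) / den,
                    (Hm[2, 1] * base_x + Hm[2, 2] * base_y + Hm[2, 3]) / den)
        },
        gamma_contrast = {
          g <- stats::runif(1, 0.7, 1.4)
          lo <- min(pair$x); hi <- max(pair$x)
          xn <- if (hi > lo) (pair$x - lo) / (hi - lo) else pair$x * 0
          list(x = xn^g * (hi - lo) + lo, y = pair$y)
        },
        normalize = {
          s <- stats::sd(pair$x); if (s == 0) s <- 1
          list(x = (pair$x - mean(pair$x)) / s, y = pair$y)
        },
        gaussian_blur = {
          sg <- stats::runif(1, 0.5, 1.2)
          x2 <- pair$x
          for (c in seq_len(dim(pair$x)[3])) x2[, , c] <- gaussian_blur_mat(pair$x[, , c], sg)
          list(x = x2, y = pair$y)
        })
    })
    names(out) <- ops
    out
  })
}

# bilinear interpolation of a coarse control-point field onto pixel coords
bilinear_field <- function(ctrl, gy, gx, qy, qx) {
  ny <- length(gy); nx <- length(gx)
  iy <- findInterval(qy, gy, rightmost.closed = TRUE)
  ix <- findInterval(qx, gx, rightmost.closed = TRUE)
  iy <- pmin(pmax(iy, 1), ny - 1); ix <- pmin(pmax(ix, 1), nx - 1)
  fy <- (qy - gy[iy]) / (gy[iy + 1] - gy[iy])
  fx <- (qx - gx[ix]) / (gx[ix + 1] - gx[ix])
  v00 <- ctrl[cbind(iy, ix)]; v10 <- ctrl[cbind(iy + 1, ix)]
  v01 <- ctrl[cbind(iy, ix + 1)]; v11 <- ctrl[cbind(iy + 1, ix + 1)]
  out <- v00 * (1 - fx) * (1 - fy) + v10 * (1 - fx) * fy +
    v01 * fx * (1 - fy) + v11 * fx * fy
  matrix(out, nrow(qy), ncol(qx))
}

solve_homography <- function(src, dst) {
  A <- matrix(0, 8, 8); bvec <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    bvec[2 * i - 1] <- u; bvec[2 * i] <- v
  }
  h <- solve(A, bvec)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Bicubic upsampling of imagery (nearest-neighbour for labels)
#'
#' @param raster an `mb_raster`.
#' @param factor scale factor (>= 1); the pixel size shrinks by this factor.
#' @param labels logical; if `TRUE`, nearest-neighbour resampling is used so
#'   mask semantics are preserved.
#' @return The upsampled `mb_raster`.
#' @export
upsample_bicubic <- function(raster, factor, labels = FALSE) {
  if (factor <= 0) stop_config("upsample factor must be positive")
  if (factor == 1) return(raster)
  raster_resample(raster, raster$pixel_size / factor,
                  method = if (labels) "nearest" else "bicubic")
}

# ---- tiled prediction ---------------------------------------------------

patch_origins <- function(len, patch, overlap_fraction) {
  if (len <= patch) return(0L)
  stride <- patch - floor(overlap_fraction * patch)
  o <- seq(0L, len - patch, by = stride)
  if (o[length(o)] != len - patch) o <- c(o, len - patch)
  as.integer(o)
}

#' Tiled prediction over a composite with overlapping patches
#'
#' The composite is covered by `patch_size` patches with the configured
#' fractional overlap (stride = `patch - floor(overlap * patch)`). Each
#' patch's probabilities are binarized at the configured threshold; a pixel
#' is classified driftwood if ANY contributing patch detects it (union rule).
#' The probability raster keeps the per-pixel maximum for diagnostics.
#'
#' @param model a `unet_model` or `unet_fit`.
#' @param composite an `mb_raster` whose bands match the model input.
#' @param config optional [seg_model_config()] override.
#' @return list with `binary` and `probability` single-band `mb_raster`s.
#' @export
predict_tiled <- function(model, composite, config = NULL) {
  if (inherits(model, "unet_fit")) model <- model$model
  config <- config %||% model$config
  if (raster_nband(composite) != model$config$input_bands)
    stop_config("composite has %d bands but the model expects %d",
                raster_nband(composite), model$config$input_bands)
  ps <- config$patch_size
  H <- raster_nrow(composite); W <- raster_ncol(composite)
  padH <- max(ps, H); padW <- max(ps, W)
  # edge-replicate so the tile is at least one patch in each dimension
  ri <- c(seq_len(H), rep(H, padH - H)); ci <- c(seq_len(W), rep(W, padW - W))
  arr <- composite$values[ri, ci, , drop = FALSE]
  prob <- matrix(0, padH, padW)
  binm <- matrix(FALSE, padH, padW)
  for (r0 in patch_origins(padH, ps, config$overlap_fraction)) {
    for (c0 in patch_origins(padW, ps, config$overlap_fraction)) {
      sub <- arr[r0 + seq_len(ps), c0 + seq_len(ps), , drop = FALSE]
      p <- predict.unet_model(model, sub)
      rows <- r0 + seq_len(ps); cols <- c0 + seq_len(ps)
      prob[rows, cols] <- pmax(prob[rows, cols], p)
      binm[rows, cols] <- binm[rows, cols] | (p >= config$binarization_threshold)
    }
  }
  prob <- prob[seq_len(H), seq_len(W)]
  binm <- binm[seq_len(H), seq_len(W)]
  list(binary = mb_raster(binm * 1, xmin = composite$xmin, ymax = composite$ymax,
                          pixel_size = composite$pixel_size, bands = "driftwood"),
       probability = mb_raster(prob, xmin = composite$xmin, ymax = composite$ymax,
                               pixel_size = composite$pixel_size, bands = "probability"))
}

#' Confusion-matrix metrics for binary rasters
#'
#' @param pred,truth logical/0-1 vectors, matrices or `mb_raster`s of equal
#'   shape; `NA`s are excluded.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `iou` and
#'   `undefined` (names of any ratios with zero denominator, reported as NaN).
#' @export
confusion_metrics <- function(pred, truth) {
  if (inherits(pred, "mb_raster")) pred <- raster_band(pred, 1)
  if (inherits(truth, "mb_raster")) truth <- raster_band(truth, 1)
  if (!isTRUE(all((dim(pred) %||% length(pred)) == (dim(truth) %||% length(truth)))))
    stop_config("confusion_metrics: shape mismatch")
  ok <- !is.na(pred) & !is.na(truth)
  p <- as.logical(pred[ok]); t <- as.logical(truth[ok])
  tp <- sum(p & t); tn <- sum(!p & !t); fp <- sum(p & !t); fn <- sum(!p & t)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  out <- list(accuracy = ratio(tp + tn, tp + tn + fp + fn),
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              iou = ratio(tp, tp + fp + fn),
              counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
  out$undefined <- names(which(vapply(out[1:4], is.nan, TRUE)))
  out
}
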