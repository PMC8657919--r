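#' Network configuration
#'
#' The default configuration is the published architecture: a stem BatchNorm
#' + 1x1 convolution, then 220 pre-activation dilated residual blocks (the
#' first 28 at 256 channels, the remaining 192 at 128), with 3x3
#' convolutions cycling through dilation factors 1, 2, 4, 8. Heads: a 1x1
#' convolution to the 10 distance classes, and full-height/width (c x 1 and
#' 1 x c) convolutions collapsing one spatial axis for the per-residue
#' auxiliary predictions (SS 9, phi 37, psi 37, ASA 11). Bottleneck widths
#' inside a block are half the block width.
#'
#' @param in_channels input tensor depth (default 547).
#' @param n_blocks number of residual blocks (default 220).
#' @param wide_blocks how many leading blocks run at \code{wide_channels}.
#' @param wide_channels,narrow_channels block widths (default 256 / 128).
#' @param dilation_cycle dilations cycled over blocks (default 1,2,4,8).
#' @param crop_size spatial crop size c (default 64).
#' @param dropout spatial dropout rate after each 3x3 convolution
#'   (default 0.15, training only).
#' @return list of class \code{"distnet_config"}.
#' @export
distnet_config <- function(in_channels = 547L, n_blocks = 220L,
                           wide_blocks = 28L, wide_channels = 256L,
                           narrow_channels = 128L,
                           dilation_cycle = c(1L, 2L, 4L, 8L),
                           crop_size = 64L, dropout = 0.15) {
  stopifnot(n_blocks >= 1, wide_blocks >= 0, wide_blocks <= n_blocks,
            wide_channels %% 2 == 0, narrow_channels %% 2 == 0,
            crop_size >= 1, dropout >= 0, dropout < 1,
            all(dilation_cycle >= 1), in_channels >= 1)
  structure(list(
    in_channels = as.integer(in_channels), n_blocks = as.integer(n_blocks),
    wide_blocks = as.integer(wide_blocks),
    wide_channels = as.integer(wide_channels),
    narrow_channels = as.integer(narrow_channels),
    dilation_cycle = as.integer(dilation_cycle),
    crop_size = as.integer(crop_size), dropout = dropout,
    heads = c(dist = 10L, ss = 9L, phi = 37L, psi = 37L, asa = 11L)),
    class = "distnet_config")
}

#' @export
print.distnet_config <- function(x, ...) {
  cat(sprintf(paste0(
    "distnet_config: %d blocks (%d @ %d ch, %d @ %d ch), dilations %s,\n",
    "  crop %d, in_channels %d, dropout %.2f\n"),
    x$n_blocks, x$wide_blocks, x$wide_channels,
    x$n_blocks - x$wide_blocks, x$narrow_channels,
    paste(x$dilation_cycle, collapse = "/"), x$crop_size, x$in_channels,
    x$dropout))
  invisible(x)
}

# per-block bookkeeping: widths, bottleneck, dilation
.block_plan <- function(cfg) {
  widths <- c(rep(cfg$wide_channels, cfg$wide_blocks),
              rep(cfg$narrow_channels, cfg$n_blocks - cfg$wide_blocks))
  # the stem 1x1 convolution outputs the first block's input width
  in_w <- c(widths[1], widths[-cfg$n_blocks])
  dil <- cfg$dilation_cycle[((seq_len(cfg$n_blocks) - 1L) %%
                               length(cfg$dilation_cycle)) + 1L]
  data.frame(block = seq_len(cfg$n_blocks), in_w = in_w, out_w = widths,
             bott = widths %/% 2L, dilation = dil)
}

.he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Build a randomly initialized model
#'
#' @param cfg a \code{\link{distnet_config}}.
#' @param seed RNG seed for the weight initialization.
#' @return list of class \code{"distnet"}: configuration, named parameter
#'   list and BatchNorm running statistics.
#' @export
build_model <- function(cfg = distnet_config(), seed = 1) {
  stopifnot(inherits(cfg, "distnet_config"))
  plan <- .block_plan(cfg)
  stem_w <- plan$in_w[1]
  .with_seed(seed, {
    p <- list(
      stem_bn_g = rep(1, cfg$in_channels), stem_bn_b = rep(0, cfg$in_channels),
      stem_w = .he_init(cfg$in_channels, stem_w), stem_b = rep(0, stem_w))
    s <- list(stem_bn_m = rep(0, cfg$in_channels),
              stem_bn_v = rep(1, cfg$in_channels))
    for (k in seq_len(cfg$n_blocks)) {
      iw <- plan$in_w[k]; ow <- plan$out_w[k]; bw <- plan$bott[k]
      pre <- sprintf("b%03d_", k)
      p[[paste0(pre, "bn1_g")]] <- rep(1, iw)
      p[[paste0(pre, "bn1_b")]] <- rep(0, iw)
      p[[paste0(pre, "w1")]] <- .he_init(iw, bw)
      p[[paste0(pre, "b1")]] <- rep(0, bw)
      p[[paste0(pre, "bn2_g")]] <- rep(1, bw)
      p[[paste0(pre, "bn2_b")]] <- rep(0, bw)
      p[[paste0(pre, "w3")]] <- .he_init(9L * bw, bw)
      p[[paste0(pre, "b3")]] <- rep(0, bw)
      p[[paste0(pre, "bn3_g")]] <- rep(1, bw)
      p[[paste0(pre, "bn3_b")]] <- rep(0, bw)
      p[[paste0(pre, "w2")]] <- .he_init(bw, ow)
      p[[paste0(pre, "b2")]] <- rep(0, ow)
      if (iw != ow) p[[paste0(pre, "wskip")]] <- .he_init(iw, ow)
      s[[paste0(pre, "bn1_m")]] <- rep(0, iw)
      s[[paste0(pre, "bn1_v")]] <- rep(1, iw)
      s[[paste0(pre, "bn2_m")]] <- rep(0, bw)
      s[[paste0(pre, "bn2_v")]] <- rep(1, bw)
      s[[paste0(pre, "bn3_m")]] <- rep(0, bw)
      s[[paste0(pre, "bn3_v")]] <- rep(1, bw)
    }
    cw <- plan$out_w[cfg$n_blocks]
    cs <- cfg$crop_size
    p$dist_w <- .he_init(cw, 10L); p$dist_b <- rep(0, 10L)
    p$auxi_w <- .he_init(cs * cw, 94L) / sqrt(cs); p$auxi_b <- rep(0, 94L)
    p$auxj_w <- .he_init(cs * cw, 94L) / sqrt(cs); p$auxj_b <- rep(0, 94L)
    structure(list(cfg = cfg, params = p, state = s, plan = plan),
              class = "distnet")
  })
}

#' @export
print.distnet <- function(x, ...) {
  print(x$cfg)
  cat(sprintf("  %s trainable parameters\n",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a \code{\link{build_model}} result.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' Block table of a model
#'
#' @param model a \code{"distnet"}.
#' @return data.frame with one row per residual block: input/output width,
#'   bottleneck width and dilation.
#' @export
model_summary <- function(model) {
  model$plan
}

#' Analytic receptive field of the block stack
#'
#' One 3x3 convolution at dilation d adds 2d cells to the receptive-field
#' diameter; the stem and 1x1 convolutions add nothing.
#'
#' @param cfg a \code{\link{distnet_config}}.
#' @return receptive-field diameter in cells.
#' @export
receptive_field <- function(cfg) {
  dil <- cfg$dilation_cycle[((seq_len(cfg$n_blocks) - 1L) %%
                               length(cfg$dilation_cycle)) + 1L]
  1L + sum(2L * dil)
}

# --- layer primitives (matrix form: npix x channels) ----------------------

.bn_fwd <- function(X, g, b, m, v, training, eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2
    m_new <- (1 - momentum) * m + momentum * mu
    v_new <- (1 - momentum) * v + momentum * va * nrow(X) / max(nrow(X) - 1, 1)
  } else {
    mu <- m; va <- v; m_new <- m; v_new <- v
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, invstd, "*")
  Y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(Y = Y, cache = list(xhat = xhat, invstd = invstd, g = g),
       m = m_new, v = v_new)
}

.bn_bwd <- function(dY, cache) {
  xhat <- cache$xhat; invstd <- cache$invstd; g <- cache$g
  n <- nrow(dY)
  dg <- colSums(dY * xhat); db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, "*")
  dX <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dY), byrow = TRUE) -
                sweep(xhat, 2, colMeans(dxhat * xhat), "*"),
              2, invstd, "*")
  list(dX = dX, dg = dg, db = db)
}

.elu_fwd <- function(X) {
  neg <- X < 0
  Y <- X
  Y[neg] <- exp(X[neg]) - 1
  list(Y = Y, cache = list(Y = Y, neg = neg))
}

.elu_bwd <- function(dY, cache) {
  dX <- dY
  dX[cache$neg] <- dY[cache$neg] * (cache$Y[cache$neg] + 1)
  dX
}

# im2col index map for a 3x3 kernel at dilation d on an H x W grid
# (0 = zero-padded source); memoized per geometry
.conv_idx_cache <- new.env(parent = emptyenv())
.conv3_idx <- function(H, W, d) {
  key <- sprintf("%d_%d_%d", H, W, d)
  if (!is.null(.conv_idx_cache[[key]])) return(.conv_idx_cache[[key]])
  i <- rep(seq_len(H), W); j <- rep(seq_len(W), each = H)
  offs <- expand.grid(a = c(-d, 0L, d), b = c(-d, 0L, d))
  idx <- matrix(0L, H * W, 9L)
  for (t in 1:9) {
    ii <- i + offs$a[t]; jj <- j + offs$b[t]
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    idx[ok, t] <- ii[ok] + (jj[ok] - 1L) * H
  }
  .conv_idx_cache[[key]] <- idx
  idx
}

.conv3_fwd <- function(X, W9, b, H, Wd, d) {
  C <- ncol(X)
  idx <- .conv3_idx(H, Wd, d)
  Xp <- rbind(0, X)
  G <- matrix(0, nrow(X), 9L * C)
  for (t in 1:9) G[, ((t - 1L) * C + 1L):(t * C)] <- Xp[idx[, t] + 1L, ]
  Y <- sweep(G %*% W9, 2, b, "+")
  list(Y = Y, cache = list(G = G, idx = idx, C = C))
}

.conv3_bwd <- function(dY, W9, cache) {
  G <- cache$G; idx <- cache$idx; C <- cache$C
  dW <- crossprod(G, dY)
  db <- colSums(dY)
  dG <- tcrossprod(dY, W9)
  dX <- matrix(0, nrow(dY), C)
  for (t in 1:9) {
    rows <- idx[, t]; sel <- rows > 0L
    dX[rows[sel], ] <- dX[rows[sel], ] +
      dG[sel, ((t - 1L) * C + 1L):(t * C)]
  }
  list(dX = dX, dW = dW, db = db)
}

.softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# collapse one spatial axis: returns H x (W*C) (axis = "i") or W x (H*C)
.collapse_axis <- function(F, H, W, axis) {
  A <- array(F, c(H, W, ncol(F)))
  if (axis == "i") t(matrix(aperm(A, c(2, 3, 1)), W * ncol(F), H))
  else            t(matrix(aperm(A, c(1, 3, 2)), H * ncol(F), W))
}

.uncollapse_axis <- function(dM, H, W, C, axis) {
  if (axis == "i") {
    A <- aperm(array(t(dM), c(W, C, H)), c(3, 1, 2))
  } else {
    A <- aperm(array(t(dM), c(H, C, W)), c(1, 3, 2))
  }
  matrix(A, H * W, C)
}

# head class segments within the 94 auxiliary channels
.AUX_SEGMENTS <- list(ss = 1:9, phi = 10:46, psi = 47:83, asa = 84:94)

#' Forward pass on one crop
#'
#' @param model a \code{"distnet"}.
#' @param x crop input: crop_size x crop_size x in_channels array.
#' @param training if TRUE, uses batch statistics, applies spatial dropout
#'   and returns a cache for \code{\link{backward}}; running BatchNorm
#'   statistics are returned updated in \code{model}.
#' @param origin 0-based (row, col) crop origin recorded in the output.
#' @return list of class \code{"crop_prediction"}: \code{dist}
#'   (c x c x 10 probabilities), \code{aux_i}, \code{aux_j} (c x 94
#'   probabilities, softmax per head segment), \code{origin}, \code{size};
#'   plus \code{cache} and updated \code{model} when training.
#' @export
forward <- function(model, x, training = FALSE, origin = c(0L, 0L)) {
  cfg <- model$cfg
  cs <- cfg$crop_size
  dmx <- dim(x)
  if (length(dmx) != 3 || dmx[3] != cfg$in_channels)
    stop(sprintf("input depth %s, expected %d channels",
                 paste(dmx, collapse = "x"), cfg$in_channels))
  if (dmx[1] != cs || dmx[2] != cs)
    stop(sprintf("spatial size %dx%d, expected crop size %d",
                 dmx[1], dmx[2], cs))
  p <- model$params; s <- model$state; plan <- model$plan
  X <- matrix(x, cs * cs, cfg$in_channels)
  cache <- if (training) list() else NULL

  bn <- .bn_fwd(X, p$stem_bn_g, p$stem_bn_b, s$stem_bn_m, s$stem_bn_v,
                training)
  if (training) {
    s$stem_bn_m <- bn$m; s$stem_bn_v <- bn$v
    cache$stem_bn <- bn$cache; cache$X0 <- X
  }
  F <- sweep(bn$Y %*% p$stem_w, 2, p$stem_b, "+")
  if (training) cache$stem_in <- bn$Y

  for (k in seq_len(cfg$n_blocks)) {
    pre <- sprintf("b%03d_", k)
    d <- plan$dilation[k]
    bn1 <- .bn_fwd(F, p[[paste0(pre, "bn1_g")]], p[[paste0(pre, "bn1_b")]],
                   s[[paste0(pre, "bn1_m")]], s[[paste0(pre, "bn1_v")]],
                   training)
    e1 <- .elu_fwd(bn1$Y)
    T1 <- sweep(e1$Y %*% p[[paste0(pre, "w1")]], 2,
                p[[paste0(pre, "b1")]], "+")
    bn2 <- .bn_fwd(T1, p[[paste0(pre, "bn2_g")]], p[[paste0(pre, "bn2_b")]],
                   s[[paste0(pre, "bn2_m")]], s[[paste0(pre, "bn2_v")]],
                   training)
    e2 <- .elu_fwd(bn2$Y)
    cv <- .conv3_fwd(e2$Y, p[[paste0(pre, "w3")]], p[[paste0(pre, "b3")]],
                     cs, cs, d)
    T3 <- cv$Y
    drop_mask <- NULL
    if (training && cfg$dropout > 0) {
      keep <- stats::runif(ncol(T3)) >= cfg$dropout
      drop_mask <- keep / (1 - cfg$dropout)
      T3 <- sweep(T3, 2, drop_mask, "*")
    }
    bn3 <- .bn_fwd(T3, p[[paste0(pre, "bn3_g")]], p[[paste0(pre, "bn3_b")]],
                   s[[paste0(pre, "bn3_m")]], s[[paste0(pre, "bn3_v")]],
                   training)
    e3 <- .elu_fwd(bn3$Y)
    T2 <- sweep(e3$Y %*% p[[paste0(pre, "w2")]], 2,
                p[[paste0(pre, "b2")]], "+")
    skip_w <- p[[paste0(pre, "wskip")]]
    skip <- if (is.null(skip_w)) F else F %*% skip_w
    Fnew <- skip + T2
    if (training) {
      s[[paste0(pre, "bn1_m")]] <- bn1$m; s[[paste0(pre, "bn1_v")]] <- bn1$v
      s[[paste0(pre, "bn2_m")]] <- bn2$m; s[[paste0(pre, "bn2_v")]] <- bn2$v
      s[[paste0(pre, "bn3_m")]] <- bn3$m; s[[paste0(pre, "bn3_v")]] <- bn3$v
      cache[[pre]] <- list(Fin = F, bn1 = bn1$cache, e1 = e1$cache,
                           e1Y = e1$Y, bn2 = bn2$cache, e2 = e2$cache,
                           e2Y = e2$Y, conv = cv$cache, d = d,
                           drop = drop_mask, bn3 = bn3$cache,
                           e3 = e3$cache, e3Y = e3$Y)
    }
    F <- Fnew
  }

  dist_z <- sweep(F %*% p$dist_w, 2, p$dist_b, "+")
  dist_p <- .softmax_rows(dist_z)
  Mi <- .collapse_axis(F, cs, cs, "i")
  Mj <- .collapse_axis(F, cs, cs, "j")
  zi <- sweep(Mi %*% p$auxi_w, 2, p$auxi_b, "+")
  zj <- sweep(Mj %*% p$auxj_w, 2, p$auxj_b, "+")
  pi_ <- zi; pj_ <- zj
  for (seg in .AUX_SEGMENTS) {
    pi_[, seg] <- .softmax_rows(zi[, seg, drop = FALSE])
    pj_[, seg] <- .softmax_rows(zj[, seg, drop = FALSE])
  }
  pred <- structure(list(
    dist = array(dist_p, c(cs, cs, 10L)),
    aux_i = pi_, aux_j = pj_,
    origin = as.integer(origin), size = cs), class = "crop_prediction")
  if (training) {
    cache$Ffinal <- F; cache$Mi <- Mi; cache$Mj <- Mj
    cache$dist_p <- dist_p; cache$aux_pi <- pi_; cache$aux_pj <- pj_
    model$state <- s
    return(list(pred = pred, cache = cache, model = model))
  }
  pred
}

#' @export
print.crop_prediction <- function(x, ...) {
  cat(sprintf("crop_prediction: %dx%d crop at origin (%d, %d)\n",
              x$size, x$size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Backward pass on one crop
#'
#' Computes parameter gradients for the softmax cross-entropy head
#' gradients \code{d_dist} (npix x 10), \code{d_auxi}, \code{d_auxj}
#' (crop x 94), already expressed on the logit scale (probability minus
#' one-hot, scaled by component weight / count).
#'
#' @param model a \code{"distnet"}.
#' @param cache cache from \code{forward(..., training = TRUE)}.
#' @param d_dist,d_auxi,d_auxj head logit gradients.
#' @return named list of gradients matching \code{model$params}, plus
#'   \code{dX} (gradient w.r.t. the input crop, npix x in_channels).
#' @export
backward <- function(model, cache, d_dist, d_auxi, d_auxj) {
  cfg <- model$cfg; p <- model$params; cs <- cfg$crop_size
  g <- list()
  F <- cache$Ffinal
  g$dist_w <- crossprod(F, d_dist); g$dist_b <- colSums(d_dist)
  dF <- tcrossprod(d_dist, p$dist_w)
  g$auxi_w <- crossprod(cache$Mi, d_auxi); g$auxi_b <- colSums(d_auxi)
  g$auxj_w <- crossprod(cache$Mj, d_auxj); g$auxj_b <- colSums(d_auxj)
  dF <- dF + .uncollapse_axis(tcrossprod(d_auxi, p$auxi_w),
                              cs, cs, ncol(F), "i")
  dF <- dF + .uncollapse_axis(tcrossprod(d_auxj, p$auxj_w),
                              cs, cs, ncol(F), "j")

  for (k in rev(seq_len(cfg$n_blocks))) {
    pre <- sprintf("b%03d_", k)
    cc <- cache[[pre]]
    dT2 <- dF
    skip_w <- p[[paste0(pre, "wskip")]]
    dFin_skip <- if (is.null(skip_w)) dF else tcrossprod(dF, skip_w)
    if (!is.null(skip_w)) g[[paste0(pre, "wskip")]] <- crossprod(cc$Fin, dF)
    g[[paste0(pre, "w2")]] <- crossprod(cc$e3Y, dT2)
    g[[paste0(pre, "b2")]] <- colSums(dT2)
    de3 <- tcrossprod(dT2, p[[paste0(pre, "w2")]])
    dbn3 <- .elu_bwd(de3, cc$e3)
    bb3 <- .bn_bwd(dbn3, cc$bn3)
    g[[paste0(pre, "bn3_g")]] <- bb3$dg
    g[[paste0(pre, "bn3_b")]] <- bb3$db
    dT3 <- bb3$dX
    if (!is.null(cc$drop)) dT3 <- sweep(dT3, 2, cc$drop, "*")
    cb <- .conv3_bwd(dT3, p[[paste0(pre, "w3")]], cc$conv)
    g[[paste0(pre, "w3")]] <- cb$dW
    g[[paste0(pre, "b3")]] <- cb$db
    dbn2 <- .elu_bwd(cb$dX, cc$e2)
    bb2 <- .bn_bwd(dbn2, cc$bn2)
    g[[paste0(pre, "bn2_g")]] <- bb2$dg
    g[[paste0(pre, "bn2_b")]] <- bb2$db
    dT1 <- bb2$dX
    g[[paste0(pre, "w1")]] <- crossprod(cc$e1Y, dT1)
    g[[paste0(pre, "b1")]] <- colSums(dT1)
    de1 <- tcrossprod(dT1, p[[paste0(pre, "w1")]])
    dbn1 <- .elu_bwd(de1, cc$e1)
    bb1 <- .bn_bwd(dbn1, cc$bn1)
    g[[paste0(pre, "bn1_g")]] <- bb1$dg
    g[[paste0(pre, "bn1_b")]] <- bb1$db
    dF <- dFin_skip + bb1$dX
  }

  g$stem_w <- crossprod(cache$stem_in, dF)
  g$stem_b <- colSums(dF)
  dbn0 <- tcrossprod(dF, p$stem_w)
  bb0 <- .bn_bwd(dbn0, cache$stem_bn)
  g$stem_bn_g <- bb0$dg
  g$stem_bn_b <- bb0$db
  g$dX <- bb0$dX
  g
}
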