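# Differentiable layer primitives composing the segmentation network.
# Tensors are base R arrays in (H, W, C, N) layout; the convolution, pooling
# and bilinear-resize kernels live in src/ops.cpp. Each forward returns the
# intermediates its backward needs, so the network backward pass is assembled
# by hand in model-backward.R (the graph is static).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

conv2d <- function(x, w, b) {
  pad <- (dim(w)[1L] - 1L) %/% 2L
  conv2d_fwd_cpp(x, w, b, pad)
}

conv2d_grad <- function(x, w, gy) {
  pad <- (dim(w)[1L] - 1L) %/% 2L
  conv2d_bwd_cpp(x, w, gy, pad)
}

# Batch normalization over (H, W, N) per channel. In training mode the batch
# statistics are used and the running statistics are updated with momentum
# 0.1; in eval mode the running statistics are used.
batchnorm_fwd <- function(z, gamma, beta, rm, rv, train, need_xhat = TRUE) {
  d <- dim(z)
  hw <- d[1L] * d[2L]
  n_per_ch <- hw * d[4L]
  if (!train && !need_xhat) {
    # inference fast path: one fused scale/shift, no normalized-tensor temp
    inv_sd <- 1 / sqrt(rv + BN_EPS)
    scale <- gamma * inv_sd
    return(list(y = z * bc_channel(scale, hw) +
                  bc_channel(beta - rm * scale, hw),
                xhat = NULL, inv_sd = inv_sd, rm = rm, rv = rv,
                n_per_ch = n_per_ch))
  }
  if (train) {
    m <- matrix(z, hw, d[3L] * d[4L])
    mu <- rowMeans(matrix(colMeans(m), d[3L], d[4L]))
    m2 <- rowMeans(matrix(colMeans(m^2), d[3L], d[4L]))
    v <- pmax(m2 - mu^2, 0)
    rm_new <- (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu
    rv_new <- (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v
  } else {
    mu <- rm; v <- rv
    rm_new <- rm; rv_new <- rv
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- (z - bc_channel(mu, hw)) * bc_channel(inv_sd, hw)
  y <- xhat * bc_channel(gamma, hw) + bc_channel(beta, hw)
  list(y = y, xhat = xhat, inv_sd = inv_sd, rm = rm_new, rv = rv_new,
       n_per_ch = n_per_ch)
}

batchnorm_bwd <- function(dy, xhat, inv_sd, gamma) {
  d <- dim(dy)
  hw <- d[1L] * d[2L]
  n_per_ch <- hw * d[4L]
  dgamma <- channel_sums(dy * xhat)
  dbeta <- channel_sums(dy)
  dxhat <- dy * bc_channel(gamma, hw)
  mean_dxhat <- channel_sums(dxhat) / n_per_ch
  mean_dxhat_xhat <- channel_sums(dxhat * xhat) / n_per_ch
  dz <- bc_channel(inv_sd, hw) *
    (dxhat - bc_channel(mean_dxhat, hw) - xhat * bc_channel(mean_dxhat_xhat, hw))
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# One conv -> batch norm -> ReLU block (3x3, padding 1 unless the stored
# kernel is 1x1). `ctx` is an environment carrying mutable running BN state
# and, when `keep`, the cache for the backward pass.
conv_block_fwd <- function(P, ctx, prefix, x, train, keep) {
  w <- P[[paste0(prefix, "_W")]]
  z <- conv2d(x, w, P[[paste0(prefix, "_b")]])
  rm_key <- paste0(prefix, "_rm"); rv_key <- paste0(prefix, "_rv")
  bn <- batchnorm_fwd(z, P[[paste0(prefix, "_g")]], P[[paste0(prefix, "_be")]],
                      ctx$state[[rm_key]], ctx$state[[rv_key]], train,
                      need_xhat = keep)
  ctx$state[[rm_key]] <- bn$rm
  ctx$state[[rv_key]] <- bn$rv
  y <- relu(bn$y)
  if (keep) {
    ctx$cache[[prefix]] <- list(x = x, xhat = bn$xhat, inv_sd = bn$inv_sd,
                                pos = bn$y > 0)
  }
  y
}

conv_block_bwd <- function(P, ctx, prefix, dy, G) {
  cache <- ctx$cache[[prefix]]
  da <- dy * cache$pos
  bnb <- batchnorm_bwd(da, cache$xhat, cache$inv_sd, P[[paste0(prefix, "_g")]])
  cg <- conv2d_grad(cache$x, P[[paste0(prefix, "_W")]], bnb$dz)
  add_grad(G, paste0(prefix, "_W"), cg$gw)
  add_grad(G, paste0(prefix, "_b"), cg$gb)
  add_grad(G, paste0(prefix, "_g"), bnb$dgamma)
  add_grad(G, paste0(prefix, "_be"), bnb$dbeta)
  cg$gx
}

add_grad <- function(G, name, value) {
  if (is.null(G$g[[name]])) G$g[[name]] <- value else G$g[[name]] <- G$g[[name]] + value
  invisible(NULL)
}

# Additive attention gate. Skip and gate maps are projected to an
# intermediate channel count by 1x1 convolutions, summed, passed through
# ReLU, projected to one channel and squashed by a sigmoid; the resulting
# mask multiplies the skip features (broadcast over channels). The gating
# signal may live on a coarser grid (the bottleneck): its projection is
# resampled bilinearly to the skip resolution. Projecting before resampling
# is mathematically identical to resampling first (1x1 convolution commutes
# with bilinear interpolation) and far cheaper in memory.
attention_gate_fwd <- function(P, ctx, prefix, skip, g, keep) {
  ax <- conv2d(skip, P[[paste0(prefix, "_Wx")]], P[[paste0(prefix, "_bx")]])
  ag <- conv2d(g, P[[paste0(prefix, "_Wg")]], P[[paste0(prefix, "_bg")]])
  sd <- dim(skip)
  if (!identical(dim(ag)[1:2], sd[1:2])) {
    ag <- resize_bilinear_fwd_cpp(ag, sd[1L], sd[2L])
  }
  a <- ax + ag
  r <- relu(a)
  u <- conv2d(r, P[[paste0(prefix, "_Wp")]], P[[paste0(prefix, "_bp")]])
  mask <- sigmoid(u)
  n_ch <- dim(skip)[3L]
  gated <- skip * mask[, , rep(1L, n_ch), , drop = FALSE]
  if (keep) {
    ctx$cache[[prefix]] <- list(skip = skip, g = g, r = r, pos = a > 0,
                                mask = mask)
  }
  list(gated = gated, mask = mask)
}

attention_gate_bwd <- function(P, ctx, prefix, dgated, G) {
  cache <- ctx$cache[[prefix]]
  d <- dim(cache$skip)
  hw <- d[1L] * d[2L]
  dskip <- dgated * cache$mask[, , rep(1L, d[3L]), , drop = FALSE]
  # d/dmask of (mask * skip), summed over the broadcast channel axis
  prod <- dgated * cache$skip
  dmask <- array(0, c(d[1L], d[2L], 1L, d[4L]))
  for (n in seq_len(d[4L])) {
    dmask[, , 1L, n] <- rowSums(matrix(prod[, , , n], hw, d[3L]))
  }
  du <- dmask * cache$mask * (1 - cache$mask)
  pb <- conv2d_grad(cache$r, P[[paste0(prefix, "_Wp")]], du)
  add_grad(G, paste0(prefix, "_Wp"), pb$gw)
  add_grad(G, paste0(prefix, "_bp"), pb$gb)
  da <- pb$gx * cache$pos
  xb <- conv2d_grad(cache$skip, P[[paste0(prefix, "_Wx")]], da)
  add_grad(G, paste0(prefix, "_Wx"), xb$gw)
  add_grad(G, paste0(prefix, "_bx"), xb$gb)
  gd <- dim(cache$g)
  dag <- if (!identical(gd[1:2], d[1:2])) {
    resize_bilinear_bwd_cpp(da, gd[1L], gd[2L])
  } else da
  gb <- conv2d_grad(cache$g, P[[paste0(prefix, "_Wg")]], dag)
  add_grad(G, paste0(prefix, "_Wg"), gb$gw)
  add_grad(G, paste0(prefix, "_bg"), gb$gb)
  list(dskip = dskip + xb$gx, dg = gb$gx)
}
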