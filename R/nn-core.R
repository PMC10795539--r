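# Minimal neural-network core: strided 2-D convolutions, transposed
# convolutions, dense layers, SGD with momentum, and selectable reconstruction
# losses. Convolution patch extraction is compiled (src/convops.cpp); all
# linear algebra is BLAS-backed matrix multiplication.
#
# Data conventions:
#   * convolutional stages carry [H, W, C, N] arrays,
#   * dense stages carry (features x N) matrices,
#   * a "flatten" / "reshape" layer converts between the two,
#   * weights: conv and convT store W as (out_c x in_c*k*k) resp.
#     (in_c x out_c*k*k), matching the im2col patch ordering (kh, kw, c).

nn_conv_out <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# Fan-in-scaled uniform init; rectifier layers get the He gain so activation
# variance is preserved through deep stacks, saturating layers the Xavier one.
nn_init <- function(nrow, ncol, fan_in, act) {
  gain <- if (act %in% c("relu", "lrelu")) sqrt(2) else 1
  lim <- gain * sqrt(3 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

nn_dense <- function(n_in, n_out, act) {
  list(type = "dense", act = act, n_in = n_in, n_out = n_out,
       W = nn_init(n_out, n_in, n_in, act), b = numeric(n_out))
}

nn_conv <- function(in_shape, out_c, k, stride, pad, act) {
  oh <- nn_conv_out(in_shape[1L], k, stride, pad)
  ow <- nn_conv_out(in_shape[2L], k, stride, pad)
  if (oh < 1L || ow < 1L)
    stop(sprintf("convolution collapses a %dx%d map below 1 pixel",
                 in_shape[1L], in_shape[2L]), call. = FALSE)
  in_c <- in_shape[3L]
  list(type = "conv", act = act, k = k, stride = stride, pad = pad,
       in_shape = in_shape, out_shape = c(oh, ow, out_c),
       W = nn_init(out_c, in_c * k * k, in_c * k * k, act),
       b = numeric(out_c))
}

# Transposed convolution targeting an explicit output height/width (so odd
# encoder sizes invert exactly); `in_shape` is the (h, w, in_c) of its input.
nn_convt <- function(in_shape, out_c, k, stride, pad, out_hw, act) {
  for (d in 1:2) {
    if (nn_conv_out(out_hw[d], k, stride, pad) != in_shape[d])
      stop(sprintf(
        "transposed convolution cannot map %d -> %d with k=%d stride=%d pad=%d",
        in_shape[d], out_hw[d], k, stride, pad), call. = FALSE)
  }
  in_c <- in_shape[3L]
  # each output pixel of a stride-s transposed conv receives ~in_c*k*k/s^2
  # contributions; use that as the effective fan-in
  fan_in <- max(1, in_c * k * k / stride^2)
  list(type = "convt", act = act, k = k, stride = stride, pad = pad,
       in_shape = in_shape, out_shape = c(out_hw[1L], out_hw[2L], out_c),
       W = nn_init(in_c, out_c * k * k, fan_in, act), b = numeric(out_c))
}

nn_flatten <- function(in_shape) {
  list(type = "flatten", in_shape = in_shape, n_out = prod(in_shape))
}

nn_reshape <- function(out_shape) {
  list(type = "reshape", out_shape = out_shape)
}

nn_act <- function(z, act) {
  switch(act,
    linear  = z,
    relu    = z * (z > 0),
    lrelu   = { a <- z; neg <- z < 0; a[neg] <- 0.01 * z[neg]; a },
    sigmoid = 1 / (1 + exp(-z)),
    stop("unknown activation: ", act, call. = FALSE))
}

nn_act_grad <- function(z, a, act) {
  switch(act,
    linear  = 1,
    relu    = (z > 0) + 0,
    lrelu   = { g <- (z > 0) + 0; g[g == 0] <- 0.01; g },
    sigmoid = a * (1 - a),
    stop("unknown activation: ", act, call. = FALSE))
}

# [H,W,C,N] array <-> (C x H*W*N) channel-major matrix used by the conv GEMMs
nn_chan_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(3L, 1L, 2L, 4L)), d[3L], d[1L] * d[2L] * d[4L])
}
nn_chan_arr <- function(m, h, w, cc, n) {
  aperm(array(m, c(cc, h, w, n)), c(2L, 3L, 1L, 4L))
}

nn_layer_forward <- function(l, x, keep = FALSE) {
  switch(l$type,
    dense = {
      z <- l$W %*% x + l$b
      a <- nn_act(z, l$act)
      list(a = a, cache = if (keep) list(x = x, z = z, a = a))
    },
    conv = {
      s <- l$in_shape; o <- l$out_shape; n <- dim(x)[4L]
      cols <- im2col_batch(x, s[1L], s[2L], s[3L], n, l$k, l$stride, l$pad,
                           o[1L], o[2L])
      z <- l$W %*% cols + l$b
      a <- nn_act(z, l$act)
      list(a = nn_chan_arr(a, o[1L], o[2L], o[3L], n),
           cache = if (keep) list(cols = cols, z = z, a = a, n = n))
    },
    convt = {
      s <- l$in_shape; o <- l$out_shape; n <- dim(x)[4L]
      x_mat <- nn_chan_mat(x)
      cols <- crossprod(l$W, x_mat)
      y <- col2im_batch(cols, o[1L], o[2L], o[3L], n, l$k, l$stride, l$pad,
                        s[1L], s[2L])
      dim(y) <- c(o[1L], o[2L], o[3L], n)
      z <- y + rep(l$b, each = o[1L] * o[2L])
      a <- nn_act(z, l$act)
      list(a = a, cache = if (keep) list(x_mat = x_mat, z = z, a = a, n = n))
    },
    flatten = {
      a <- x; dim(a) <- c(l$n_out, dim(x)[4L])
      list(a = a, cache = if (keep) list(n = dim(x)[4L]))
    },
    reshape = {
      a <- x; dim(a) <- c(l$out_shape, ncol(x))
      list(a = a, cache = if (keep) list(n = ncol(x)))
    })
}

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- nn_layer_forward(layers[[i]], x, keep = training)
    x <- r$a
    if (training) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_layer_backward <- function(l, cache, da) {
  switch(l$type,
    dense = {
      dz <- da * nn_act_grad(cache$z, cache$a, l$act)
      list(dW = tcrossprod(dz, cache$x), db = rowSums(dz),
           dx = crossprod(l$W, dz))
    },
    conv = {
      s <- l$in_shape; o <- l$out_shape; n <- cache$n
      da_m <- nn_chan_mat(da)
      dz <- da_m * nn_act_grad(cache$z, cache$a, l$act)
      dx <- col2im_batch(crossprod(l$W, dz), s[1L], s[2L], s[3L], n,
                         l$k, l$stride, l$pad, o[1L], o[2L])
      dim(dx) <- c(s, n)
      list(dW = tcrossprod(dz, cache$cols), db = rowSums(dz), dx = dx)
    },
    convt = {
      s <- l$in_shape; o <- l$out_shape; n <- cache$n
      dz <- da * nn_act_grad(cache$z, cache$a, l$act)
      db <- rowSums(nn_chan_mat(dz))
      cols_dz <- im2col_batch(dz, o[1L], o[2L], o[3L], n, l$k, l$stride,
                              l$pad, s[1L], s[2L])
      dW <- tcrossprod(cache$x_mat, cols_dz)
      dx <- nn_chan_arr(l$W %*% cols_dz, s[1L], s[2L], s[3L], n)
      list(dW = dW, db = db, dx = dx)
    },
    flatten = {
      dx <- da; dim(dx) <- c(l$in_shape, cache$n)
      list(dW = NULL, db = NULL, dx = dx)
    },
    reshape = {
      dx <- da; dim(dx) <- c(prod(l$out_shape), cache$n)
      list(dW = NULL, db = NULL, dx = dx)
    })
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  da <- dout
  for (i in rev(seq_along(layers))) {
    g <- nn_layer_backward(layers[[i]], caches[[i]], da)
    grads[[i]] <- list(dW = g$dW, db = g$db)
    da <- g$dx
  }
  grads
}

nn_sgd_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W)) NULL
    else list(vW = array(0, dim(l$W)), vb = numeric(length(l$b)))
  })
}

nn_sgd_step <- function(layers, grads, state, lr, momentum) {
  for (i in seq_along(layers)) {
    if (is.null(layers[[i]]$W)) next
    st <- state[[i]]
    st$vW <- momentum * st$vW - lr * grads[[i]]$dW
    st$vb <- momentum * st$vb - lr * grads[[i]]$db
    layers[[i]]$W <- layers[[i]]$W + st$vW
    layers[[i]]$b <- layers[[i]]$b + st$vb
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

nn_n_params <- function(layers) {
  sum(vapply(layers, function(l)
    if (is.null(l$W)) 0 else length(l$W) + length(l$b), numeric(1)))
}

# ---- reconstruction losses -------------------------------------------------
# Each loss maps (reconstruction, target) arrays of identical shape (last
# dimension = sample) to list(value, grad) with grad the same shape as the
# reconstruction.

nn_loss_mse <- function(y, x) {
  d <- y - x
  list(value = mean(d * d), grad = array(2 * d / length(d), dim(y)))
}

# Global (whole-image) structural similarity, averaged over the batch; the
# training loss is 1 - SSIM. Constants follow the usual convention for a
# [0,1] dynamic range.
nn_loss_ssim <- function(y, x, c1 = 0.01^2, c2 = 0.03^2) {
  dims <- dim(y)
  n_s <- dims[length(dims)]
  npix <- prod(dims) / n_s
  ym <- matrix(y, npix, n_s); xm <- matrix(x, npix, n_s)
  mu_y <- colMeans(ym); mu_x <- colMeans(xm)
  yc <- sweep(ym, 2L, mu_y); xc <- sweep(xm, 2L, mu_x)
  var_y <- colMeans(yc * yc); var_x <- colMeans(xc * xc)
  cov_xy <- colMeans(xc * yc)
  a1 <- 2 * mu_x * mu_y + c1; a2 <- 2 * cov_xy + c2
  b1 <- mu_x^2 + mu_y^2 + c1; b2 <- var_x + var_y + c2
  ssim <- (a1 * a2) / (b1 * b2)
  # dS/dy_i per sample, from the quotient rule on the global statistics
  t1 <- sweep(xc, 2L, a1 / (b1 * b2), `*`) +
        matrix(rep(a2 * mu_x / (b1 * b2), each = npix), npix, n_s)
  t2 <- matrix(rep(ssim * mu_y / b1, each = npix), npix, n_s) +
        sweep(yc, 2L, ssim / b2, `*`)
  ds_dy <- (2 / npix) * (t1 - t2)
  grad <- array(-ds_dy / n_s, dims)
  list(value = mean(1 - ssim), grad = grad)
}

nn_loss <- function(name) {
  switch(name,
    mse  = nn_loss_mse,
    ssim = nn_loss_ssim,
    perceptual = stop(
      "perceptual loss needs a pretrained feature-extractor network whose ",
      "weights are not bundled with this package; use loss = \"mse\" or ",
      "\"ssim\" instead", call. = FALSE),
    stop("unknown loss: ", name, call. = FALSE))
}
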