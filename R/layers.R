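# Layer primitives with hand-derived backward passes.
#
# Minibatch tensors are plain R arrays and the inner products are batched
# matrix products, so BLAS does the work and no layer loops over trials.
# The user-facing input is [N, C, T] (trials, channels, time); inside the
# trunk the map/filter axis comes FIRST so that batch-norm statistics and
# pointwise mixing are plain row operations:
#   conv_temporal:  [N, C, T]      -> [F1, N, C, T]
#   conv_spatial:   [F1, N, C, T]  -> [M, N, T]       (M = F1 * D)
#   separable/pool: [M, N, T]      -> [F2, N, T2]
# and [F2, N, T2] doubles as the LSTM input sequence (d x N slices per t).

same_pad <- function(kw) {
  left <- (kw - 1L) %/% 2L
  c(left = left, right = kw - 1L - left)
}

# batched im2col along time: x [N, C, T] -> [kw, N*C*T]
time_im2col <- function(x, kw) {
  d <- dim(x)
  pad <- same_pad(kw)
  xp <- array(0, c(d[1], d[2], d[3] + kw - 1L))
  xp[, , pad["left"] + seq_len(d[3])] <- x
  xcol <- matrix(0, kw, prod(d))
  for (o in seq_len(kw)) {
    xcol[o, ] <- xp[, , o:(o + d[3] - 1L)]
  }
  xcol
}

# temporal convolution: F1 kernels of length kw along time, same padding,
# shared across channels, no bias; the im2col matrix is cached for backward
conv_temporal_fwd <- function(x, k) {
  d <- dim(x)
  xcol <- time_im2col(x, ncol(k))
  list(y = array(k %*% xcol, c(nrow(k), d)), xcol = xcol)
}

conv_temporal_bwd <- function(x, k, dy, xcol) {
  d <- dim(x)
  kw <- ncol(k); f1 <- nrow(k)
  pad <- same_pad(kw)
  dym <- matrix(dy, f1)
  dk <- tcrossprod(dym, xcol)
  dxcol <- crossprod(k, dym)                  # [kw, N*C*T]
  dxp <- array(0, c(d[1], d[2], d[3] + kw - 1L))
  for (o in seq_len(kw)) {
    cols <- o:(o + d[3] - 1L)
    dxp[, , cols] <- dxp[, , cols] + dxcol[o, ]   # same (n, c, t) ordering
  }
  list(dx = dxp[, , pad["left"] + seq_len(d[3]), drop = FALSE], dk = dk)
}

# depthwise spatial convolution: per temporal filter f, D kernels spanning
# all channels (valid, collapses the channel axis), no bias
conv_spatial_fwd <- function(x, wd) {
  d <- dim(x)                                 # [F1, N, C, T]
  f1 <- dim(wd)[1]; dd <- dim(wd)[2]
  xa <- aperm(x, c(3, 2, 4, 1))               # [C, N, T, F1]: f contiguous
  y <- array(0, c(f1 * dd, d[2], d[4]))
  for (f in seq_len(f1)) {
    m <- matrix(xa[, , , f], d[3])            # [C, N*T]
    rows <- ((f - 1L) * dd + 1L):(f * dd)
    y[rows, , ] <- matrix(wd[f, , ], dd) %*% m
  }
  y
}

conv_spatial_bwd <- function(x, wd, dy) {
  d <- dim(x)
  f1 <- dim(wd)[1]; dd <- dim(wd)[2]
  xa <- aperm(x, c(3, 2, 4, 1))
  dwd <- array(0, dim(wd))
  dxa <- array(0, dim(xa))
  for (f in seq_len(f1)) {
    m <- matrix(xa[, , , f], d[3])
    rows <- ((f - 1L) * dd + 1L):(f * dd)
    dyf <- matrix(dy[rows, , ], dd)
    dwd[f, , ] <- tcrossprod(dyf, m)
    dxa[, , , f] <- crossprod(matrix(wd[f, , ], dd), dyf)  # [C, N*T]
  }
  list(dx = aperm(dxa, c(4, 2, 1, 3)), dwd = dwd)
}

# separable convolution, depthwise half: one length-ks kernel per map,
# same padding along time; x [M, N, T]
conv_sepdepth_fwd <- function(x, wsd) {
  d <- dim(x)
  ks <- ncol(wsd)
  pad <- same_pad(ks)
  xp <- array(0, c(d[1], d[2], d[3] + ks - 1L))
  xp[, , pad["left"] + seq_len(d[3])] <- x
  y <- array(0, d)
  for (o in seq_len(ks)) {
    y <- y + wsd[, o] * xp[, , o:(o + d[3] - 1L), drop = FALSE]
  }
  y
}

conv_sepdepth_bwd <- function(x, wsd, dy) {
  d <- dim(x)
  ks <- ncol(wsd)
  pad <- same_pad(ks)
  xp <- array(0, c(d[1], d[2], d[3] + ks - 1L))
  xp[, , pad["left"] + seq_len(d[3])] <- x
  dwsd <- matrix(0, d[1], ks)
  dxp <- array(0, dim(xp))
  for (o in seq_len(ks)) {
    cols <- o:(o + d[3] - 1L)
    dwsd[, o] <- rowSums(matrix(dy * xp[, , cols, drop = FALSE], d[1]))
    dxp[, , cols] <- dxp[, , cols] + wsd[, o] * dy
  }
  list(dx = dxp[, , pad["left"] + seq_len(d[3]), drop = FALSE], dwsd = dwsd)
}

# pointwise (1x1) convolution mixing maps: x [M, N, T] -> [F2, N, T]
conv_pointwise_fwd <- function(x, wsp) {
  d <- dim(x)
  array(wsp %*% matrix(x, d[1]), c(nrow(wsp), d[2], d[3]))
}

conv_pointwise_bwd <- function(x, wsp, dy) {
  d <- dim(x)
  dym <- matrix(dy, nrow(wsp))
  list(dx = array(crossprod(wsp, dym), d),
       dwsp = tcrossprod(dym, matrix(x, d[1])))
}

# batch normalization over the leading (map) axis of an [F, ...] array
bn_fwd <- function(x, gamma, beta, running, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  f <- d[1]
  xm <- matrix(x, f)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean
    va <- running$var
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * ivar
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, ivar = ivar, gamma = gamma, dims = d,
                           training = training),
       running = running)
}

bn_bwd <- function(dy, cache) {
  d <- cache$dims
  dym <- matrix(dy, d[1])
  xhat <- cache$xhat; ivar <- cache$ivar; gamma <- cache$gamma
  dgamma <- rowSums(dym * xhat)
  dbeta <- rowSums(dym)
  dxhat <- dym * gamma
  dxm <- if (cache$training) {
    # batch statistics depend on x: full backward
    ivar * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    # running statistics are constants at inference
    ivar * dxhat
  }
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

elu_fwd <- function(x) {
  y <- x
  neg <- x < 0
  y[neg] <- exp(x[neg]) - 1
  y
}

elu_bwd <- function(y, dy) {
  g <- dy
  neg <- y < 0
  g[neg] <- dy[neg] * (y[neg] + 1)
  g
}

# non-overlapping average pooling along the last axis of [M, N, T];
# remainder truncated
pool_fwd <- function(x, p) {
  d <- dim(x)
  tw <- d[3] %/% p
  xt <- x[, , seq_len(tw * p), drop = FALSE]
  arr <- array(xt, c(d[1], d[2], p, tw))
  y <- colMeans(aperm(arr, c(3, 1, 2, 4)))
  array(y, c(d[1], d[2], tw))
}

pool_bwd <- function(dy, p, t_in) {
  d <- dim(dy)
  tw <- d[3]
  dx <- array(0, c(d[1], d[2], t_in))
  for (q in seq_len(p)) {
    dx[, , (seq_len(tw) - 1L) * p + q] <- dy / p
  }
  dx
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

# dense layer in columns-as-samples orientation: z [in, N] -> [out, N]
dense_fwd <- function(z, w, b) {
  w %*% z + b
}

dense_bwd <- function(z, w, dy) {
  list(dz = crossprod(w, dy), dw = tcrossprod(dy, z), db = rowSums(dy))
}

# softmax over rows of an [N, K] matrix
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(probs, y) {
  # y: 0-based labels
  n <- nrow(probs)
  p <- probs[cbind(seq_len(n), y + 1L)]
  -mean(log(pmax(p, 1e-300)))
}

softmax_ce_bwd <- function(probs, y) {
  n <- nrow(probs)
  d <- probs
  d[cbind(seq_len(n), y + 1L)] <- d[cbind(seq_len(n), y + 1L)] - 1
  d / n
}

glorot <- function(nr, nc_fan, dims) {
  lim <- sqrt(6 / (nr + nc_fan))
  array(stats::runif(prod(dims), -lim, lim), dims)
}
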