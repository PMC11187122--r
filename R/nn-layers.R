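# Native neural-network layer primitives.
#
# Tensors use column-major R arrays with layout (channels/filters, time,
# batch). Each layer is a list with a $type and its parameter arrays; forward
# passes return the output plus a cache consumed by the matching backward
# pass. No external deep-learning runtime is involved: convolutions are
# im2col + GEMM, so all heavy lifting lands in BLAS.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Swish activation
#'
#' `swish(x) = x * sigmoid(x)` — the smooth, non-monotonic activation used
#' between convolutional layers of the autoencoder and predictor.
#'
#' @param x Numeric vector/array.
#' @return Same shape as `x`.
#' @export
swish <- function(x) x * sigmoid(x)

swish_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

## ---- initialisers -----------------------------------------------------

glorot_uniform <- function(nrow, ncol, fan_in = ncol, fan_out = nrow) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

## ---- conv1d -----------------------------------------------------------

# "same"-style padding so that out_len == ceiling(in_len / stride)
conv_pad <- function(in_len, kernel, stride) {
  out_len <- ceiling(in_len / stride)
  total <- max((out_len - 1L) * stride + kernel - in_len, 0L)
  c(left = total %/% 2L, right = total - total %/% 2L)
}

layer_conv1d <- function(in_channels, filters, kernel = 5L, stride = 1L) {
  list(
    type = "conv1d",
    kernel = as.integer(kernel), stride = as.integer(stride),
    in_channels = as.integer(in_channels), filters = as.integer(filters),
    params = list(
      W = glorot_uniform(filters, in_channels * kernel),
      b = numeric(filters)
    ),
    trainable = TRUE
  )
}

conv1d_im2col_index <- function(C, Tin, kernel, stride) {
  pad <- conv_pad(Tin, kernel, stride)
  Tp <- Tin + pad[["left"]] + pad[["right"]]
  Tout <- ceiling(Tin / stride)
  # row offsets within one patch: channel fastest, then tap
  v <- rep.int(seq_len(C), kernel) + C * rep(seq_len(kernel) - 1L, each = C)
  starts <- (seq_len(Tout) - 1L) * stride            # 0-based in padded time
  idx <- outer(v, starts * C, "+")                   # (C*k) x Tout
  list(idx = as.vector(idx), pad = pad, Tp = Tp, Tout = Tout)
}

conv1d_forward <- function(layer, x) {
  d <- dim(x); C <- d[1]; Tin <- d[2]; N <- d[3]
  k <- layer$kernel; s <- layer$stride
  ii <- conv1d_im2col_index(C, Tin, k, s)
  xp <- array(0, c(C, ii$Tp, N))
  xp[, ii$pad[["left"]] + seq_len(Tin), ] <- x
  dim(xp) <- c(C * ii$Tp, N)
  patches <- xp[ii$idx, , drop = FALSE]              # (C*k*Tout) x N
  dim(patches) <- c(C * k, ii$Tout * N)
  out <- layer$params$W %*% patches + layer$params$b
  dim(out) <- c(layer$filters, ii$Tout, N)
  list(out = out, cache = list(patches = patches, idx = ii, C = C,
                               Tin = Tin, N = N))
}

conv1d_backward <- function(layer, cache, dout) {
  k <- layer$kernel; C <- cache$C; N <- cache$N; ii <- cache$idx
  dim(dout) <- c(layer$filters, ii$Tout * N)
  dW <- dout %*% t(cache$patches)
  db <- rowSums(dout)
  dpatch <- crossprod(layer$params$W, dout)          # (C*k) x (Tout*N)
  dim(dpatch) <- c(C * k * ii$Tout, N)
  agg <- rowsum(dpatch, group = ii$idx)              # sorted unique idx
  dxp <- matrix(0, C * ii$Tp, N)
  dxp[as.integer(rownames(agg)), ] <- agg
  dim(dxp) <- c(C, ii$Tp, N)
  dx <- dxp[, ii$pad[["left"]] + seq_len(cache$Tin), , drop = FALSE]
  list(grads = list(W = dW, b = db), dx = dx)
}

## ---- batch normalisation ---------------------------------------------

layer_batchnorm <- function(filters, momentum = 0.9, eps = 1e-5) {
  list(
    type = "batchnorm", filters = as.integer(filters),
    momentum = momentum, eps = eps,
    params = list(gamma = rep(1, filters), beta = rep(0, filters)),
    running_mean = rep(0, filters), running_var = rep(1, filters),
    trainable = TRUE
  )
}

batchnorm_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1], prod(d[-1]))
  if (training) {
    m <- rowMeans(xm)
    v <- rowMeans(xm * xm) - m * m
    layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * m
    layer$running_var <- layer$momentum * layer$running_var + (1 - layer$momentum) * v
  } else {
    m <- layer$running_mean
    v <- layer$running_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- (xm - m) * inv_sd
  out <- layer$params$gamma * xhat + layer$params$beta
  dim(out) <- d
  list(out = out, cache = list(xhat = xhat, inv_sd = inv_sd, d = d),
       layer = layer)
}

batchnorm_backward <- function(layer, cache, dout) {
  d <- cache$d
  dim(dout) <- c(d[1], prod(d[-1]))
  xhat <- cache$xhat
  dgamma <- rowSums(dout * xhat)
  dbeta <- rowSums(dout)
  g <- layer$params$gamma * cache$inv_sd
  dx <- g * (dout - rowMeans(dout) - xhat * rowMeans(dout * xhat))
  dim(dx) <- d
  list(grads = list(gamma = dgamma, beta = dbeta), dx = dx)
}

## ---- activation / dropout / upsampling --------------------------------

layer_swish <- function() list(type = "swish", trainable = FALSE)

swish_forward <- function(layer, x) list(out = swish(x), cache = list(x = x))
swish_backward <- function(layer, cache, dout) {
  list(grads = NULL, dx = dout * swish_grad(cache$x))
}

# drops whole feature maps per sample (spatial dropout)
layer_spatial_dropout <- function(rate) {
  list(type = "spatial_dropout", rate = rate, trainable = FALSE)
}

spatial_dropout_forward <- function(layer, x, training) {
  if (!training || layer$rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  d <- dim(x)
  keep <- matrix(stats::rbinom(d[1] * d[3], 1L, 1 - layer$rate), d[1], d[3])
  mask <- keep / (1 - layer$rate)
  big <- mask[, rep(seq_len(d[3]), each = d[2]), drop = FALSE]
  dim(x) <- c(d[1], d[2] * d[3])
  out <- x * big
  dim(out) <- d
  list(out = out, cache = list(mask = big, d = d))
}

spatial_dropout_backward <- function(layer, cache, dout) {
  if (is.null(cache$mask)) return(list(grads = NULL, dx = dout))
  d <- cache$d
  dim(dout) <- c(d[1], d[2] * d[3])
  dx <- dout * cache$mask
  dim(dx) <- d
  list(grads = NULL, dx = dx)
}

# nearest-neighbour repetition along time
layer_upsample <- function(factor) {
  list(type = "upsample", factor = as.integer(factor), trainable = FALSE)
}

upsample_forward <- function(layer, x) {
  d <- dim(x)
  out <- x[, rep(seq_len(d[2]), each = layer$factor), , drop = FALSE]
  list(out = out, cache = list(d = d))
}

upsample_backward <- function(layer, cache, dout) {
  d <- cache$d; u <- layer$factor
  dim(dout) <- c(d[1], u, d[2], d[3])
  dx <- colSums(aperm(dout, c(2, 1, 3, 4)))
  list(grads = NULL, dx = dx)
}

## ---- BiLSTM -----------------------------------------------------------

# Gate layout in the stacked weight matrices: input, forget, cell, output.
lstm_dir_params <- function(input_dim, units) {
  b <- numeric(4 * units)
  b[units + seq_len(units)] <- 1          # forget-gate bias 1
  list(
    W = glorot_uniform(4 * units, input_dim),
    U = glorot_uniform(4 * units, units),
    b = b
  )
}

layer_bilstm <- function(input_dim, units) {
  fw <- lstm_dir_params(input_dim, units)
  bw <- lstm_dir_params(input_dim, units)
  list(
    type = "bilstm", units = as.integer(units),
    input_dim = as.integer(input_dim),
    params = list(Wf = fw$W, Uf = fw$U, bf = fw$b,
                  Wb = bw$W, Ub = bw$U, bb = bw$b),
    trainable = TRUE
  )
}

lstm_dir_forward <- function(W, U, b, x, reverse) {
  d <- dim(x); Tt <- d[2]; N <- d[3]
  H <- nrow(U) %/% 4L
  order_t <- if (reverse) rev(seq_len(Tt)) else seq_len(Tt)
  h <- matrix(0, H, N); cc <- matrix(0, H, N)
  steps <- vector("list", Tt)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (step in seq_len(Tt)) {
    t <- order_t[step]
    xt <- x[, t, ]
    if (is.null(dim(xt))) dim(xt) <- c(d[1], N)
    z <- W %*% xt + U %*% h + b
    ig <- sigmoid(z[i1, , drop = FALSE])
    fg <- sigmoid(z[i2, , drop = FALSE])
    gg <- tanh(z[i3, , drop = FALSE])
    og <- sigmoid(z[i4, , drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- fg * c_prev + ig * gg
    tc <- tanh(cc)
    h <- og * tc
    steps[[step]] <- list(t = t, xt = xt, ig = ig, fg = fg, gg = gg, og = og,
                          c_prev = c_prev, h_prev = h_prev, tc = tc)
  }
  list(h_last = h, steps = steps, H = H, Tt = Tt, N = N, D = d[1])
}

lstm_dir_backward <- function(W, U, b, fwd, dh_last) {
  H <- fwd$H; N <- fwd$N; Tt <- fwd$Tt; D <- fwd$D
  dW <- matrix(0, 4 * H, D); dU <- matrix(0, 4 * H, H); db <- numeric(4 * H)
  dx <- array(0, c(D, Tt, N))
  dh <- dh_last
  dc <- matrix(0, H, N)
  i1 <- seq_len(H); i2 <- H + i1; i3 <- 2L * H + i1; i4 <- 3L * H + i1
  for (step in rev(seq_len(Tt))) {
    st <- fwd$steps[[step]]
    dog <- dh * st$tc
    dct <- dc + dh * st$og * (1 - st$tc^2)
    dig <- dct * st$gg
    dfg <- dct * st$c_prev
    dgg <- dct * st$ig
    dc <- dct * st$fg
    dz <- rbind(dig * st$ig * (1 - st$ig),
                dfg * st$fg * (1 - st$fg),
                dgg * (1 - st$gg^2),
                dog * st$og * (1 - st$og))
    dW <- dW + dz %*% t(st$xt)
    dU <- dU + dz %*% t(st$h_prev)
    db <- db + rowSums(dz)
    dx[, st$t, ] <- crossprod(W, dz)
    dh <- crossprod(U, dz)
  }
  list(dW = dW, dU = dU, db = db, dx = dx)
}

bilstm_forward <- function(layer, x) {
  p <- layer$params
  fw <- lstm_dir_forward(p$Wf, p$Uf, p$bf, x, reverse = FALSE)
  bw <- lstm_dir_forward(p$Wb, p$Ub, p$bb, x, reverse = TRUE)
  list(out = rbind(fw$h_last, bw$h_last), cache = list(fw = fw, bw = bw))
}

bilstm_backward <- function(layer, cache, dout) {
  H <- layer$units
  p <- layer$params
  gf <- lstm_dir_backward(p$Wf, p$Uf, p$bf, cache$fw,
                          dout[seq_len(H), , drop = FALSE])
  gb <- lstm_dir_backward(p$Wb, p$Ub, p$bb, cache$bw,
                          dout[H + seq_len(H), , drop = FALSE])
  list(grads = list(Wf = gf$dW, Uf = gf$dU, bf = gf$db,
                    Wb = gb$dW, Ub = gb$dU, bb = gb$db),
       dx = gf$dx + gb$dx)
}

## ---- dense ------------------------------------------------------------

layer_dense <- function(input_dim, units) {
  list(
    type = "dense", input_dim = as.integer(input_dim),
    units = as.integer(units),
    params = list(W = glorot_uniform(units, input_dim), b = numeric(units)),
    trainable = TRUE
  )
}

dense_forward <- function(layer, x) {
  list(out = layer$params$W %*% x + layer$params$b, cache = list(x = x))
}

dense_backward <- function(layer, cache, dout) {
  list(grads = list(W = dout %*% t(cache$x), b = rowSums(dout)),
       dx = crossprod(layer$params$W, dout))
}

## ---- network dispatch --------------------------------------------------

#' Run a network forward
#'
#' @param net A network as built by [build_dcae()] or [build_predictor()].
#' @param x Input array `(channels, time, batch)`.
#' @param training Logical; enables batch statistics and dropout. Layers with
#'   `inference_only = TRUE` (a frozen encoder) always run in inference mode.
#' @return List with `out`, per-layer `caches` and the (possibly updated) `net`.
#' @keywords internal
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    tr <- training && !isTRUE(ly$inference_only)
    r <- switch(ly$type,
      conv1d = conv1d_forward(ly, x),
      batchnorm = batchnorm_forward(ly, x, tr),
      swish = swish_forward(ly, x),
      spatial_dropout = spatial_dropout_forward(ly, x, tr),
      upsample = upsample_forward(ly, x),
      bilstm = bilstm_forward(ly, x),
      dense = dense_forward(ly, x),
      stop("unknown layer type: ", ly$type)
    )
    if (!is.null(r$layer)) net$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches, net = net)
}

# returns list(grads = per-layer grads (NULL for frozen/param-free), dx)
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    r <- switch(ly$type,
      conv1d = conv1d_backward(ly, caches[[i]], dout),
      batchnorm = batchnorm_backward(ly, caches[[i]], dout),
      swish = swish_backward(ly, caches[[i]], dout),
      spatial_dropout = spatial_dropout_backward(ly, caches[[i]], dout),
      upsample = upsample_backward(ly, caches[[i]], dout),
      bilstm = bilstm_backward(ly, caches[[i]], dout),
      dense = dense_backward(ly, caches[[i]], dout)
    )
    grads[i] <- list(if (isTRUE(ly$trainable)) r$grads else NULL)
    dout <- r$dx
  }
  list(grads = grads, dx = dout)
}

## ---- losses -----------------------------------------------------------

# y: integer class labels (1-based), logits (K x N)
softmax_xent <- function(logits, y) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  n <- ncol(logits)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(n))], 1e-12)))
  donehot <- matrix(0, nrow(logits), n)
  donehot[cbind(y, seq_len(n))] <- 1
  list(loss = loss, grad = (p - donehot) / n, probs = p)
}

mse_loss <- function(yhat, y) {
  d <- yhat - y
  list(loss = mean(d * d), grad = 2 * d / length(d))
}
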