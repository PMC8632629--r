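# Minimal feed-forward / convolutional / recurrent network engine.
#
# Networks are lists of layer records; forward passes return caches
# that the backward passes consume.  All heavy lifting is BLAS-backed
# matrix multiplication: 1-D and 2-D convolutions run through im2col
# patch matrices, the LSTM through per-step gate matrices.  Training
# uses minibatch Adam on the softmax cross-entropy.
#
# Shapes:
#   dense input          B x D matrix
#   conv1d input         array (C_in, L, B)
#   conv2d input         array (C_in, H, W, B)
#   lstm input           array (D, k, B)  (k timesteps)

glorot <- function(fan_in, fan_out, dims) {
  s <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -s, s), dim = dims)
}

nn_dense <- function(d_in, d_out, activation = "relu") {
  list(type = "dense", activation = activation,
       W = glorot(d_in, d_out, c(d_in, d_out)),
       b = matrix(0, 1, d_out))
}

nn_conv1d <- function(c_in, filters, kernel) {
  list(type = "conv1d", c_in = c_in, filters = filters, kernel = kernel,
       W = glorot(c_in * kernel, filters, c(c_in * kernel, filters)),
       b = matrix(0, filters, 1))
}

nn_pool1d <- function(width = 2L) list(type = "pool1d", width = as.integer(width))

nn_conv2d <- function(c_in, filters, kernel) {
  list(type = "conv2d", c_in = c_in, filters = filters, kernel = kernel,
       W = glorot(c_in * kernel^2, filters, c(c_in * kernel^2, filters)),
       b = matrix(0, filters, 1))
}

nn_pool2d <- function() list(type = "pool2d")

nn_flatten <- function() list(type = "flatten")

nn_lstm <- function(d_in, hidden) {
  list(type = "lstm", d_in = d_in, hidden = hidden,
       Wx = glorot(d_in, hidden, c(d_in, 4 * hidden)),
       Wh = glorot(hidden, hidden, c(hidden, 4 * hidden)),
       b = matrix(0, 1, 4 * hidden))
}

layer_params <- function(layer) {
  switch(layer$type,
         dense = c("W", "b"),
         conv1d = c("W", "b"),
         conv2d = c("W", "b"),
         lstm = c("Wx", "Wh", "b"),
         character(0))
}

# ---- forward -------------------------------------------------------------

fwd_dense <- function(layer, x) {
  z <- x %*% layer$W
  z <- sweep(z, 2, layer$b, "+")
  out <- if (layer$activation == "relu") z * (z > 0) else z
  list(out = out, cache = list(x = x, z = z))
}

im2col1d <- function(a, kernel) {
  d <- dim(a)                       # (C, L, B)
  l_out <- d[2] - kernel + 1L
  m <- matrix(0, d[1] * kernel, l_out * d[3])
  for (o in 0:(kernel - 1L))
    m[(o * d[1] + 1L):((o + 1L) * d[1]), ] <-
      a[, (1L + o):(l_out + o), , drop = FALSE]
  m
}

fwd_conv1d <- function(layer, a) {
  d <- dim(a)
  l_out <- d[2] - layer$kernel + 1L
  m <- im2col1d(a, layer$kernel)
  z <- crossprod(layer$W, m) + matrix(layer$b, layer$filters, l_out * d[3])
  out <- array(z * (z > 0), dim = c(layer$filters, l_out, d[3]))
  list(out = out, cache = list(m = m, z = z, dim_in = d, l_out = l_out))
}

fwd_pool1d <- function(layer, a) {
  d <- dim(a)
  wd <- layer$width
  p <- d[2] %/% wd
  idx <- function(off) seq.int(off, wd * p, wd)
  out <- a[, idx(1L), , drop = FALSE]
  which_ <- array(1L, dim = dim(out))
  if (wd > 1L) for (q in 2:wd) {
    cand <- a[, idx(q), , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    which_[upd] <- q
  }
  list(out = out, cache = list(which_ = which_, dim_in = d, p = p, wd = wd))
}

im2col2d <- function(a, kernel) {
  d <- dim(a)                       # (C, H, W, B)
  h_out <- d[2] - kernel + 1L
  w_out <- d[3] - kernel + 1L
  m <- matrix(0, d[1] * kernel * kernel, h_out * w_out * d[4])
  r <- 0L
  for (ow in 0:(kernel - 1L)) {
    for (oh in 0:(kernel - 1L)) {
      m[(r * d[1] + 1L):((r + 1L) * d[1]), ] <-
        a[, (1L + oh):(h_out + oh), (1L + ow):(w_out + ow), , drop = FALSE]
      r <- r + 1L
    }
  }
  m
}

fwd_conv2d <- function(layer, a) {
  d <- dim(a)
  h_out <- d[2] - layer$kernel + 1L
  w_out <- d[3] - layer$kernel + 1L
  m <- im2col2d(a, layer$kernel)
  z <- crossprod(layer$W, m) +
    matrix(layer$b, layer$filters, h_out * w_out * d[4])
  out <- array(z * (z > 0), dim = c(layer$filters, h_out, w_out, d[4]))
  list(out = out, cache = list(m = m, z = z, dim_in = d,
                               h_out = h_out, w_out = w_out))
}

fwd_pool2d <- function(layer, a) {
  d <- dim(a)
  ph <- d[2] %/% 2L; pw <- d[3] %/% 2L
  ih1 <- seq.int(1L, 2L * ph, 2L); ih2 <- ih1 + 1L
  iw1 <- seq.int(1L, 2L * pw, 2L); iw2 <- iw1 + 1L
  cand <- list(a[, ih1, iw1, , drop = FALSE], a[, ih2, iw1, , drop = FALSE],
               a[, ih1, iw2, , drop = FALSE], a[, ih2, iw2, , drop = FALSE])
  out <- cand[[1]]; which_ <- array(1L, dim = dim(out))
  for (q in 2:4) {
    upd <- cand[[q]] > out
    out[upd] <- cand[[q]][upd]
    which_[upd] <- q
  }
  list(out = out, cache = list(which_ = which_, dim_in = d, ph = ph, pw = pw,
                               ih1 = ih1, ih2 = ih2, iw1 = iw1, iw2 = iw2))
}

fwd_flatten <- function(layer, a) {
  d <- dim(a)
  nd <- length(d)
  b <- d[nd]
  out <- t(matrix(a, prod(d[-nd]), b))
  list(out = out, cache = list(dim_in = d))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

fwd_lstm <- function(layer, a) {
  d <- dim(a)                       # (D, k, B)
  k <- d[2]; B <- d[3]; H <- layer$hidden
  h <- matrix(0, B, H); cs <- matrix(0, B, H)
  steps <- vector("list", k)
  for (t in seq_len(k)) {
    xt <- t(matrix(a[, t, , drop = FALSE], d[1], B))   # B x D
    z <- xt %*% layer$Wx + h %*% layer$Wh +
      matrix(layer$b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cs
    cs <- f * c_prev + i * g
    tc <- tanh(cs)
    h_prev <- h
    h <- o * tc
    steps[[t]] <- list(xt = xt, i = i, f = f, o = o, g = g,
                       c_prev = c_prev, cs = cs, tc = tc, h_prev = h_prev)
  }
  list(out = h, cache = list(steps = steps, dims = d))
}

nn_forward <- function(layers, x, want_cache = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
                dense = fwd_dense(l, x),
                conv1d = fwd_conv1d(l, x),
                pool1d = fwd_pool1d(l, x),
                conv2d = fwd_conv2d(l, x),
                pool2d = fwd_pool2d(l, x),
                flatten = fwd_flatten(l, x),
                lstm = fwd_lstm(l, x))
    x <- r$out
    if (want_cache) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

# ---- backward ------------------------------------------------------------

bwd_dense <- function(layer, cache, dout) {
  if (layer$activation == "relu") dout <- dout * (cache$z > 0)
  list(grads = list(W = crossprod(cache$x, dout),
                    b = matrix(colSums(dout), 1)),
       dx = dout %*% t(layer$W))
}

col2im1d <- function(dm, dim_in, kernel, l_out) {
  da <- array(0, dim = dim_in)
  for (o in 0:(kernel - 1L)) {
    blk <- array(dm[(o * dim_in[1] + 1L):((o + 1L) * dim_in[1]), ],
                 dim = c(dim_in[1], l_out, dim_in[3]))
    da[, (1L + o):(l_out + o), ] <-
      da[, (1L + o):(l_out + o), , drop = FALSE] + blk
  }
  da
}

bwd_conv1d <- function(layer, cache, dout) {
  dz <- matrix(dout, layer$filters, cache$l_out * cache$dim_in[3])
  dz <- dz * (cache$z > 0)
  dW <- cache$m %*% t(dz)
  db <- matrix(rowSums(dz), ncol = 1)
  dm <- layer$W %*% dz
  list(grads = list(W = dW, b = db),
       dx = col2im1d(dm, cache$dim_in, layer$kernel, cache$l_out))
}

bwd_pool1d <- function(layer, cache, dout) {
  da <- array(0, dim = cache$dim_in)
  p <- cache$p; wd <- cache$wd
  for (q in seq_len(wd))
    da[, seq.int(q, wd * p, wd), ] <- dout * (cache$which_ == q)
  list(grads = NULL, dx = da)
}

bwd_conv2d <- function(layer, cache, dout) {
  n_pos <- cache$h_out * cache$w_out * cache$dim_in[4]
  dz <- matrix(dout, layer$filters, n_pos)
  dz <- dz * (cache$z > 0)
  dW <- cache$m %*% t(dz)
  db <- matrix(rowSums(dz), ncol = 1)
  dm <- layer$W %*% dz
  da <- array(0, dim = cache$dim_in)
  r <- 0L
  for (ow in 0:(layer$kernel - 1L)) {
    for (oh in 0:(layer$kernel - 1L)) {
      blk <- array(dm[(r * cache$dim_in[1] + 1L):((r + 1L) * cache$dim_in[1]), ],
                   dim = c(cache$dim_in[1], cache$h_out, cache$w_out,
                           cache$dim_in[4]))
      sl_h <- (1L + oh):(cache$h_out + oh)
      sl_w <- (1L + ow):(cache$w_out + ow)
      da[, sl_h, sl_w, ] <- da[, sl_h, sl_w, , drop = FALSE] + blk
      r <- r + 1L
    }
  }
  list(grads = list(W = dW, b = db), dx = da)
}

bwd_pool2d <- function(layer, cache, dout) {
  da <- array(0, dim = cache$dim_in)
  for (q in 1:4) {
    sel <- (cache$which_ == q) * dout
    ih <- if (q %in% c(1L, 3L)) cache$ih1 else cache$ih2
    iw <- if (q <= 2L) cache$iw1 else cache$iw2
    da[, ih, iw, ] <- da[, ih, iw, , drop = FALSE] + sel
  }
  list(grads = NULL, dx = da)
}

bwd_flatten <- function(layer, cache, dout) {
  list(grads = NULL, dx = array(t(dout), dim = cache$dim_in))
}

bwd_lstm <- function(layer, cache, dout) {
  d <- cache$dims
  k <- d[2]; B <- d[3]; H <- layer$hidden
  dWx <- array(0, dim = dim(layer$Wx))
  dWh <- array(0, dim = dim(layer$Wh))
  db <- matrix(0, 1, 4 * H)
  dh <- dout
  dc <- matrix(0, B, H)
  dxa <- array(0, dim = d)
  for (t in rev(seq_len(k))) {
    s <- cache$steps[[t]]
    dc <- dc + dh * s$o * (1 - s$tc^2)
    do_ <- dh * s$tc
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dz <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                do_ * s$o * (1 - s$o),
                dg * (1 - s$g^2))
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dxa[, t, ] <- t(dz %*% t(layer$Wx))
    dh <- dz %*% t(layer$Wh)
    dc <- dc * s$f
  }
  list(grads = list(Wx = dWx, Wh = dWh, b = db), dx = dxa)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$type,
                dense = bwd_dense(l, caches[[i]], dout),
                conv1d = bwd_conv1d(l, caches[[i]], dout),
                pool1d = bwd_pool1d(l, caches[[i]], dout),
                conv2d = bwd_conv2d(l, caches[[i]], dout),
                pool2d = bwd_pool2d(l, caches[[i]], dout),
                flatten = bwd_flatten(l, caches[[i]], dout),
                lstm = bwd_lstm(l, caches[[i]], dout))
    grads[i] <- list(r$grads)
    dout <- r$dx
  }
  grads
}

# ---- loss & optimizer ----------------------------------------------------

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and its gradient w.r.t. the logits
ce_loss <- function(logits, y_idx) {
  p <- softmax(logits)
  B <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(B), y_idx)] + eps))
  dlog <- p
  dlog[cbind(seq_len(B), y_idx)] <- dlog[cbind(seq_len(B), y_idx)] - 1
  list(loss = loss, dlogits = dlog / B, prob = p)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    ps <- layer_params(l)
    if (length(ps) == 0L) return(NULL)
    st <- lapply(ps, function(p) list(m = array(0, dim = dim(l[[p]])),
                                      v = array(0, dim = dim(l[[p]]))))
    names(st) <- ps
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    ps <- layer_params(layers[[i]])
    for (p in ps) {
      g <- grads[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mh / (sqrt(vh) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}
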