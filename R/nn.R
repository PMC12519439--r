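# Minimal sequence-network engine: 1-D convolution, batch normalization,
# LSTM/GRU cells with bidirectional wrappers, dense layers, softmax
# cross-entropy and Adam. Tensors are (batch, time, channels) arrays stored
# column-major; matrices are (batch, features). Every layer carries $params
# and $grads as parallel named lists so the optimizer can walk them
# generically. Gradients are verified against finite differences in the
# test suite.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# (B,T,C) -> (B,C) slice at time t without dimension dropping
arr_t <- function(X, t) {
  d <- dim(X)
  matrix(X[, t, ], d[1], d[3])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- layer constructors -------------------------------------------------

layer_conv1d <- function(c_in, filters, kernel = 9, act = "relu") {
  list(type = "conv1d", c_in = c_in, filters = filters, kernel = kernel,
       act = act,
       params = list(W = glorot(kernel * c_in, filters),
                     b = numeric(filters)),
       grads = NULL, cache = NULL)
}

layer_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", channels = channels, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, channels), beta = numeric(channels)),
       running_mean = numeric(channels), running_var = rep(1, channels),
       grads = NULL, cache = NULL)
}

rnn_cell_params <- function(type, c_in, H) {
  ng <- if (type == "lstm") 4L else 3L
  b <- numeric(ng * H)
  if (type == "lstm") b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(Wx = glorot(c_in, ng * H), Wh = glorot(H, ng * H), b = b)
}

layer_rnn <- function(cell = c("lstm", "gru"), c_in, H, return_seq = TRUE,
                      bidirectional = FALSE, dropout = 0) {
  cell <- match.arg(cell)
  p <- rnn_cell_params(cell, c_in, H)
  if (bidirectional) {
    pb <- rnn_cell_params(cell, c_in, H)
    params <- list(Wx = p$Wx, Wh = p$Wh, b = p$b,
                   Wx_r = pb$Wx, Wh_r = pb$Wh, b_r = pb$b)
  } else {
    params <- p
  }
  list(type = "rnn", cell = cell, c_in = c_in, H = H, return_seq = return_seq,
       bidirectional = bidirectional, dropout = dropout,
       params = params, grads = NULL, cache = NULL)
}

layer_dense <- function(d_in, d_out, act = "linear") {
  list(type = "dense", d_in = d_in, d_out = d_out, act = act,
       params = list(W = glorot(d_in, d_out), b = numeric(d_out)),
       grads = NULL, cache = NULL)
}

layer_gap <- function() list(type = "gap", params = list(), grads = NULL,
                             cache = NULL)

## ---- conv1d -------------------------------------------------------------

conv1d_fwd <- function(layer, X, train) {
  d <- dim(X); B <- d[1]; T_ <- d[2]; C <- d[3]
  k <- layer$kernel
  pl <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, T_ + k - 1L, C))
  Xp[, pl + seq_len(T_), ] <- X
  Xc <- matrix(0, B * T_, k * C)
  for (j in seq_len(k)) {
    sl <- Xp[, j + seq_len(T_) - 1L, , drop = FALSE]
    Xc[, (j - 1L) * C + seq_len(C)] <- matrix(sl, B * T_, C)
  }
  Z <- Xc %*% layer$params$W
  Z <- sweep(Z, 2, layer$params$b, "+")
  A <- if (layer$act == "relu") pmax(Z, 0) else Z
  layer$cache <- list(Xc = Xc, Z = Z, B = B, T_ = T_, C = C)
  out <- A
  dim(out) <- c(B, T_, layer$filters)
  list(layer = layer, out = out)
}

conv1d_bwd <- function(layer, dOut) {
  cc <- layer$cache
  B <- cc$B; T_ <- cc$T_; C <- cc$C; k <- layer$kernel
  dA <- matrix(dOut, B * T_, layer$filters)
  dZ <- if (layer$act == "relu") dA * (cc$Z > 0) else dA
  layer$grads <- list(W = crossprod(cc$Xc, dZ), b = colSums(dZ))
  dXc <- dZ %*% t(layer$params$W)
  pl <- (k - 1L) %/% 2L
  dXp <- array(0, c(B, T_ + k - 1L, C))
  for (j in seq_len(k)) {
    blk <- array(dXc[, (j - 1L) * C + seq_len(C)], c(B, T_, C))
    dXp[, j + seq_len(T_) - 1L, ] <- dXp[, j + seq_len(T_) - 1L, , drop = FALSE] + blk
  }
  dX <- dXp[, pl + seq_len(T_), , drop = FALSE]
  dim(dX) <- c(B, T_, C)
  list(layer = layer, dX = dX)
}

## ---- batch normalization ------------------------------------------------

bn_fwd <- function(layer, X, train) {
  d <- dim(X)
  Xm <- if (length(d) == 3L) matrix(X, d[1] * d[2], d[3]) else X
  if (train) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm^2) - mu^2
    layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv_std <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(Xm, 2, mu, "-"), 2, inv_std, "*")
  Y <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
  layer$cache <- list(xhat = xhat, inv_std = inv_std, dims = d, train = train)
  if (length(d) == 3L) dim(Y) <- d
  list(layer = layer, out = Y)
}

bn_bwd <- function(layer, dOut) {
  cc <- layer$cache
  d <- cc$dims
  dY <- if (length(d) == 3L) matrix(dOut, d[1] * d[2], d[3]) else dOut
  xhat <- cc$xhat
  N <- nrow(dY)
  layer$grads <- list(gamma = colSums(dY * xhat), beta = colSums(dY))
  dxhat <- sweep(dY, 2, layer$params$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- sweep(dxhat * N, 2, s1, "-") - sweep(xhat, 2, s2, "*")
  dX <- sweep(dX, 2, cc$inv_std / N, "*")
  if (length(d) == 3L) dim(dX) <- d
  list(layer = layer, dX = dX)
}

## ---- recurrent cells ----------------------------------------------------

lstm_cell_fwd <- function(p, X) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  H <- ncol(p$Wh) %/% 4L
  h <- matrix(0, B, H); cs <- matrix(0, B, H)
  Y <- array(0, c(B, T_, H))
  steps <- vector("list", T_)
  for (t in seq_len(T_)) {
    Xt <- arr_t(X, t)
    A <- Xt %*% p$Wx + h %*% p$Wh
    A <- sweep(A, 2, p$b, "+")
    i <- sigmoid(A[, seq_len(H), drop = FALSE])
    f <- sigmoid(A[, H + seq_len(H), drop = FALSE])
    g <- tanh(A[, 2 * H + seq_len(H), drop = FALSE])
    o <- sigmoid(A[, 3 * H + seq_len(H), drop = FALSE])
    c_prev <- cs
    cs <- f * cs + i * g
    tc <- tanh(cs)
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = c_prev, tc = tc,
                       h_prev = h)
    h <- o * tc
    Y[, t, ] <- h
  }
  list(Y = Y, last = h, steps = steps)
}

lstm_cell_bwd <- function(p, X, fwd, dY, dLast) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  H <- ncol(p$Wh) %/% 4L
  gWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  gWh <- matrix(0, H, 4L * H)
  gb <- numeric(4L * H)
  dX <- array(0, dim(X))
  dh_next <- if (is.null(dLast)) matrix(0, B, H) else dLast
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    st <- fwd$steps[[t]]
    dh <- dh_next
    if (!is.null(dY)) dh <- dh + arr_t(dY, t)
    do <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dA <- cbind(di * st$i * (1 - st$i), df * st$f * (1 - st$f),
                dg * (1 - st$g^2), do * st$o * (1 - st$o))
    Xt <- arr_t(X, t)
    gWx <- gWx + crossprod(Xt, dA)
    gWh <- gWh + crossprod(st$h_prev, dA)
    gb <- gb + colSums(dA)
    dX[, t, ] <- dA %*% t(p$Wx)
    dh_next <- dA %*% t(p$Wh)
    dc_next <- dc * st$f
  }
  list(gWx = gWx, gWh = gWh, gb = gb, dX = dX)
}

gru_cell_fwd <- function(p, X) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  H <- ncol(p$Wh) %/% 3L
  h <- matrix(0, B, H)
  Y <- array(0, c(B, T_, H))
  steps <- vector("list", T_)
  iz <- seq_len(H); ir <- H + seq_len(H); in_ <- 2 * H + seq_len(H)
  for (t in seq_len(T_)) {
    Xt <- arr_t(X, t)
    Ax <- sweep(Xt %*% p$Wx, 2, p$b, "+")
    Ah <- h %*% p$Wh
    z <- sigmoid(Ax[, iz, drop = FALSE] + Ah[, iz, drop = FALSE])
    r <- sigmoid(Ax[, ir, drop = FALSE] + Ah[, ir, drop = FALSE])
    hn_lin <- Ah[, in_, drop = FALSE]
    n <- tanh(Ax[, in_, drop = FALSE] + r * hn_lin)
    h_prev <- h
    h <- (1 - z) * n + z * h
    steps[[t]] <- list(z = z, r = r, n = n, hn_lin = hn_lin, h_prev = h_prev)
    Y[, t, ] <- h
  }
  list(Y = Y, last = h, steps = steps)
}

gru_cell_bwd <- function(p, X, fwd, dY, dLast) {
  d <- dim(X); B <- d[1]; T_ <- d[2]
  H <- ncol(p$Wh) %/% 3L
  iz <- seq_len(H); ir <- H + seq_len(H); in_ <- 2 * H + seq_len(H)
  gWx <- matrix(0, nrow(p$Wx), 3L * H)
  gWh <- matrix(0, H, 3L * H)
  gb <- numeric(3L * H)
  dX <- array(0, dim(X))
  dh_next <- if (is.null(dLast)) matrix(0, B, H) else dLast
  for (t in rev(seq_len(T_))) {
    st <- fwd$steps[[t]]
    dh <- dh_next
    if (!is.null(dY)) dh <- dh + arr_t(dY, t)
    dz <- dh * (st$h_prev - st$n)
    dn <- dh * (1 - st$z)
    dAn <- dn * (1 - st$n^2)
    dr <- dAn * st$hn_lin
    dhn_lin <- dAn * st$r
    dAz <- dz * st$z * (1 - st$z)
    dAr <- dr * st$r * (1 - st$r)
    dA <- cbind(dAz, dAr, dAn)
    Xt <- arr_t(X, t)
    gWx <- gWx + crossprod(Xt, dA)
    gb <- gb + colSums(dA)
    dAh <- cbind(dAz, dAr, dhn_lin)
    gWh <- gWh + crossprod(st$h_prev, dAh)
    dX[, t, ] <- dA %*% t(p$Wx)
    dh_next <- dh * st$z + dAh %*% t(p$Wh)
  }
  list(gWx = gWx, gWh = gWh, gb = gb, dX = dX)
}

rev_time <- function(X) X[, rev(seq_len(dim(X)[2])), , drop = FALSE]

rnn_fwd <- function(layer, X, train) {
  cf <- if (layer$cell == "lstm") lstm_cell_fwd else gru_cell_fwd
  p_f <- list(Wx = layer$params$Wx, Wh = layer$params$Wh, b = layer$params$b)
  f <- cf(p_f, X)
  if (layer$bidirectional) {
    Xr <- rev_time(X)
    p_r <- list(Wx = layer$params$Wx_r, Wh = layer$params$Wh_r,
                b = layer$params$b_r)
    r <- cf(p_r, Xr)
    if (layer$return_seq) {
      out <- array(0, c(dim(X)[1], dim(X)[2], 2L * layer$H))
      out[, , seq_len(layer$H)] <- f$Y
      out[, , layer$H + seq_len(layer$H)] <- rev_time(r$Y)
    } else {
      out <- cbind(f$last, r$last)
    }
    layer$cache <- list(X = X, Xr = Xr, f = f, r = r)
  } else {
    out <- if (layer$return_seq) f$Y else f$last
    layer$cache <- list(X = X, f = f)
  }
  if (train && layer$dropout > 0) {
    mask <- array(stats::rbinom(length(out), 1, 1 - layer$dropout),
                  dim = dim(out) %||% c(nrow(out), ncol(out)))
    out <- out * mask / (1 - layer$dropout)
    layer$cache$mask <- mask
  }
  list(layer = layer, out = out)
}

rnn_bwd <- function(layer, dOut) {
  cc <- layer$cache
  if (!is.null(cc$mask)) dOut <- dOut * cc$mask / (1 - layer$dropout)
  cb <- if (layer$cell == "lstm") lstm_cell_bwd else gru_cell_bwd
  H <- layer$H
  p_f <- list(Wx = layer$params$Wx, Wh = layer$params$Wh, b = layer$params$b)
  if (layer$bidirectional) {
    p_r <- list(Wx = layer$params$Wx_r, Wh = layer$params$Wh_r,
                b = layer$params$b_r)
    if (layer$return_seq) {
      dYf <- dOut[, , seq_len(H), drop = FALSE]
      dYr <- rev_time(dOut[, , H + seq_len(H), drop = FALSE])
      bf <- cb(p_f, cc$X, cc$f, dYf, NULL)
      br <- cb(p_r, cc$Xr, cc$r, dYr, NULL)
    } else {
      bf <- cb(p_f, cc$X, cc$f, NULL, dOut[, seq_len(H), drop = FALSE])
      br <- cb(p_r, cc$Xr, cc$r, NULL, dOut[, H + seq_len(H), drop = FALSE])
    }
    layer$grads <- list(Wx = bf$gWx, Wh = bf$gWh, b = bf$gb,
                        Wx_r = br$gWx, Wh_r = br$gWh, b_r = br$gb)
    dX <- bf$dX + rev_time(br$dX)
  } else {
    if (layer$return_seq) {
      bf <- cb(p_f, cc$X, cc$f, dOut, NULL)
    } else {
      bf <- cb(p_f, cc$X, cc$f, NULL, dOut)
    }
    layer$grads <- list(Wx = bf$gWx, Wh = bf$gWh, b = bf$gb)
    dX <- bf$dX
  }
  list(layer = layer, dX = dX)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- dense & pooling ----------------------------------------------------

dense_fwd <- function(layer, X, train) {
  Z <- sweep(X %*% layer$params$W, 2, layer$params$b, "+")
  A <- if (layer$act == "relu") pmax(Z, 0) else Z
  layer$cache <- list(X = X, Z = Z)
  list(layer = layer, out = A)
}

dense_bwd <- function(layer, dOut) {
  cc <- layer$cache
  dZ <- if (layer$act == "relu") dOut * (cc$Z > 0) else dOut
  layer$grads <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
  list(layer = layer, dX = dZ %*% t(layer$params$W))
}

gap_fwd <- function(layer, X, train) {
  d <- dim(X)
  layer$cache <- list(dims = d)
  out <- matrix(0, d[1], d[3])
  for (c in seq_len(d[3])) out[, c] <- rowMeans(matrix(X[, , c], d[1], d[2]))
  list(layer = layer, out = out)
}

gap_bwd <- function(layer, dOut) {
  d <- layer$cache$dims
  dX <- array(0, d)
  for (t in seq_len(d[2])) dX[, t, ] <- dOut / d[2]
  list(layer = layer, dX = dX)
}

## ---- network-level plumbing --------------------------------------------

nn_layer_fwd <- function(layer, X, train) {
  switch(layer$type,
         conv1d = conv1d_fwd(layer, X, train),
         batchnorm = bn_fwd(layer, X, train),
         rnn = rnn_fwd(layer, X, train),
         dense = dense_fwd(layer, X, train),
         gap = gap_fwd(layer, X, train))
}

nn_layer_bwd <- function(layer, dOut) {
  switch(layer$type,
         conv1d = conv1d_bwd(layer, dOut),
         batchnorm = bn_bwd(layer, dOut),
         rnn = rnn_bwd(layer, dOut),
         dense = dense_bwd(layer, dOut),
         gap = gap_bwd(layer, dOut))
}

nn_forward <- function(net, X, train = FALSE) {
  for (i in seq_along(net$layers)) {
    res <- nn_layer_fwd(net$layers[[i]], X, train)
    net$layers[[i]] <- res$layer
    X <- res$out
  }
  list(net = net, logits = X)
}

nn_backward <- function(net, dLogits) {
  d <- dLogits
  for (i in rev(seq_along(net$layers))) {
    res <- nn_layer_bwd(net$layers[[i]], d)
    net$layers[[i]] <- res$layer
    d <- res$dX
  }
  net
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss and logit gradient for one-hot rows of Y.
softmax_ce <- function(logits, Y) {
  p <- softmax_rows(logits)
  loss <- -mean(rowSums(Y * log(pmax(p, 1e-12))))
  list(loss = loss, dLogits = (p - Y) / nrow(Y), probs = p)
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(net) {
  lapply(net$layers, function(l) {
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(net, state, t, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- net$layers[[i]]$grads
    if (is.null(g) || !length(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g[[nm]]
      st$v <- b2 * st$v + (1 - b2) * g[[nm]]^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}

# Strip per-batch caches so trained networks serialize small.
nn_clear_cache <- function(net) {
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$cache <- NULL
    net$layers[[i]]$grads <- NULL
  }
  net
}
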