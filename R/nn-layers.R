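## Minimal reverse-mode neural network engine.
##
## The fusion network needs exact control over its architecture and
## gradients (adaptive fusion weights, Grad-CAM feature-map gradients,
## input-space saliency), so the layers are implemented directly on BLAS
## matrix operations: 3x3 same-padding convolution via im2col, batch
## normalisation, 2x2 max pooling, residual blocks, global average pooling,
## dense layers, single-head scaled-dot-product self-attention and a
## single-layer LSTM. Parameters live in one flat named list; every layer
## has an `init`, a `forward` (returning output + cache) and a `backward`
## (returning input gradient + parameter gradients), which makes the whole
## model differentiable end to end and numerically checkable.
##
## Tensor layouts: images channel-first (C, H, W, N) so per-channel
## reshapes are contiguous; vectors (N, d); pulse (N, T).

sigm <- function(x) 1 / (1 + exp(-x))

## ---- layer specs ------------------------------------------------------

spec_dense <- function(id, d_in, d_out, act = "none")
  list(type = "dense", id = id, d_in = d_in, d_out = d_out, act = act)
spec_conv3 <- function(id, c_in, c_out)
  list(type = "conv3", id = id, c_in = c_in, c_out = c_out)
spec_bn2d <- function(id, c) list(type = "bn2d", id = id, c = c)
spec_relu4 <- function() list(type = "relu4", id = "")
spec_maxpool2 <- function() list(type = "maxpool2", id = "")
spec_gap <- function() list(type = "gap", id = "")
spec_resblock <- function(id, c) list(type = "resblock", id = id, c = c)
spec_attn <- function(id, tokens, d, out = "flatten")
  list(type = "attn", id = id, tokens = tokens, d = d, out = out)
spec_lstm <- function(id, d_in, h, readout = "mean")
  list(type = "lstm", id = id, d_in = d_in, h = h, readout = readout)

## ---- init -------------------------------------------------------------

layer_init <- function(sp) {
  id <- sp$id
  switch(sp$type,
    dense = setNames(list(
      matrix(rnorm(sp$d_in * sp$d_out, 0, sqrt(2 / sp$d_in)), sp$d_in, sp$d_out),
      numeric(sp$d_out)), paste0(id, c(".W", ".b"))),
    conv3 = setNames(list(
      matrix(rnorm(sp$c_out * 9 * sp$c_in, 0, sqrt(2 / (9 * sp$c_in))),
             sp$c_out, 9 * sp$c_in),
      numeric(sp$c_out)), paste0(id, c(".W", ".b"))),
    bn2d = setNames(list(rep(1, sp$c), rep(0, sp$c)),
                    paste0(id, c(".gamma", ".beta"))),
    attn = setNames(lapply(1:3, function(i)
      matrix(rnorm(sp$d * sp$d, 0, sqrt(1 / sp$d)), sp$d, sp$d)),
      paste0(id, c(".Wq", ".Wk", ".Wv"))),
    lstm = {
      k <- 1 / sqrt(sp$h)
      b <- numeric(4 * sp$h); b[sp$h + seq_len(sp$h)] <- 1  # forget bias
      setNames(list(
        matrix(runif(4 * sp$h * sp$d_in, -k, k), 4 * sp$h, sp$d_in),
        matrix(runif(4 * sp$h * sp$h, -k, k), 4 * sp$h, sp$h),
        b), paste0(id, c(".Wx", ".Wh", ".b")))
    },
    resblock = c(layer_init(spec_conv3(paste0(id, ".c1"), sp$c, sp$c)),
                 layer_init(spec_bn2d(paste0(id, ".b1"), sp$c)),
                 layer_init(spec_conv3(paste0(id, ".c2"), sp$c, sp$c)),
                 layer_init(spec_bn2d(paste0(id, ".b2"), sp$c))),
    list())
}

layer_state_init <- function(sp) {
  switch(sp$type,
    bn2d = setNames(list(rep(0, sp$c), rep(1, sp$c)),
                    paste0(sp$id, c(".mean", ".var"))),
    resblock = c(layer_state_init(spec_bn2d(paste0(sp$id, ".b1"), sp$c)),
                 layer_state_init(spec_bn2d(paste0(sp$id, ".b2"), sp$c))),
    list())
}

## ---- conv3 ------------------------------------------------------------

## patch matrix (9C x HWN) of a (C, H, W, N) tensor, zero padding 1
im2col3 <- function(x) {
  im2col3_cpp(x, dim(x))
}

conv3_fwd <- function(sp, P_, x) {
  d <- dim(x); H <- d[2]; W <- d[3]; N <- d[4]
  Pm <- im2col3(x)
  Y <- P_[[paste0(sp$id, ".W")]] %*% Pm + P_[[paste0(sp$id, ".b")]]
  dim(Y) <- c(sp$c_out, H, W, N)
  list(y = Y, cache = list(dims = d, P = Pm))
}

conv3_bwd <- function(sp, P_, cache, dy) {
  d <- cache$dims; C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Co <- sp$c_out
  dYm <- dy; dim(dYm) <- c(Co, H * W * N)
  gW <- tcrossprod(dYm, cache$P)
  gb <- rowSums(dYm)
  ## input gradient as a convolution of dy with the flipped kernel
  W_ <- P_[[paste0(sp$id, ".W")]]
  dim(W_) <- c(Co, C, 9)
  Wb <- aperm(W_[, , 9:1, drop = FALSE], c(2, 1, 3))  # (C, Co, 9 flipped)
  dim(Wb) <- c(C, 9 * Co)
  dx <- Wb %*% im2col3(dy)
  dim(dx) <- d
  list(dx = dx, grads = setNames(list(gW, gb), paste0(sp$id, c(".W", ".b"))))
}

## ---- batch norm -------------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn2d_fwd <- function(sp, P_, S_, x, train) {
  d <- dim(x); C <- d[1]; M <- d[2] * d[3] * d[4]
  xm <- x; dim(xm) <- c(C, M)
  gamma <- P_[[paste0(sp$id, ".gamma")]]
  beta <- P_[[paste0(sp$id, ".beta")]]
  state_updates <- NULL
  if (train) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu^2
    v[v < 0] <- 0
    state_updates <- setNames(list(
      (1 - BN_MOMENTUM) * S_[[paste0(sp$id, ".mean")]] + BN_MOMENTUM * mu,
      (1 - BN_MOMENTUM) * S_[[paste0(sp$id, ".var")]] + BN_MOMENTUM * v),
      paste0(sp$id, c(".mean", ".var")))
  } else {
    mu <- S_[[paste0(sp$id, ".mean")]]
    v <- S_[[paste0(sp$id, ".var")]]
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- (xm - mu) * invstd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d, train = train),
       state_updates = state_updates)
}

bn2d_bwd <- function(sp, P_, cache, dy) {
  d <- cache$dims; C <- d[1]; M <- d[2] * d[3] * d[4]
  dym <- dy; dim(dym) <- c(C, M)
  gamma <- P_[[paste0(sp$id, ".gamma")]]
  xhat <- cache$xhat
  ggamma <- rowSums(dym * xhat)
  gbeta <- rowSums(dym)
  dxhat <- dym * gamma
  if (cache$train) {
    dxm <- (cache$invstd / M) * (M * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  } else {
    dxm <- dxhat * cache$invstd
  }
  dim(dxm) <- d
  list(dx = dxm, grads = setNames(list(ggamma, gbeta),
                                  paste0(sp$id, c(".gamma", ".beta"))))
}

## ---- simple layers ----------------------------------------------------

relu_fwd <- function(x) list(y = x * (x > 0), cache = list(mask = x > 0))
relu_bwd <- function(cache, dy) list(dx = dy * cache$mask, grads = list())

maxpool2_fwd <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[2], 2); i2 <- seq(2, d[2], 2)
  j1 <- seq(1, d[3], 2); j2 <- seq(2, d[3], 2)
  s1 <- x[, i1, j1, , drop = FALSE]; s2 <- x[, i2, j1, , drop = FALSE]
  s3 <- x[, i1, j2, , drop = FALSE]; s4 <- x[, i2, j2, , drop = FALSE]
  y <- pmax(s1, s2, s3, s4)
  w1 <- s1 == y; w2 <- (s2 == y) & !w1; w3 <- (s3 == y) & !(w1 | w2)
  w4 <- !(w1 | w2 | w3)
  list(y = y, cache = list(w = list(w1, w2, w3, w4), dims = d))
}

maxpool2_bwd <- function(cache, dy) {
  d <- cache$dims
  i1 <- seq(1, d[2], 2); i2 <- seq(2, d[2], 2)
  j1 <- seq(1, d[3], 2); j2 <- seq(2, d[3], 2)
  dx <- array(0, d)
  route <- function(wk) { t <- array(0, dim(dy)); t[wk] <- dy[wk]; t }
  dx[, i1, j1, ] <- dx[, i1, j1, , drop = FALSE] + route(cache$w[[1]])
  dx[, i2, j1, ] <- dx[, i2, j1, , drop = FALSE] + route(cache$w[[2]])
  dx[, i1, j2, ] <- dx[, i1, j2, , drop = FALSE] + route(cache$w[[3]])
  dx[, i2, j2, ] <- dx[, i2, j2, , drop = FALSE] + route(cache$w[[4]])
  list(dx = dx, grads = list())
}

gap_fwd <- function(x) {
  d <- dim(x)  # (C, H, W, N)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  m <- x; dim(m) <- c(C * HW, N)
  y <- matrix(0, N, C)
  cm <- matrix(0, C, HW)
  for (n in seq_len(N)) {
    cm[] <- m[, n]
    y[n, ] <- rowMeans(cm)
  }
  list(y = y, cache = list(dims = d))
}

gap_bwd <- function(cache, dy) {
  d <- cache$dims
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  dx <- aperm(array(t(dy) / HW, c(C, N, HW)), c(1, 3, 2))
  dim(dx) <- d
  list(dx = dx, grads = list())
}

dense_fwd <- function(sp, P_, x) {
  z <- x %*% P_[[paste0(sp$id, ".W")]] +
    rep(P_[[paste0(sp$id, ".b")]], each = nrow(x))
  y <- if (sp$act == "relu") z * (z > 0) else z
  list(y = y, cache = list(x = x, z = if (sp$act == "relu") z else NULL))
}

dense_bwd <- function(sp, P_, cache, dy) {
  dz <- if (sp$act == "relu") dy * (cache$z > 0) else dy
  list(dx = tcrossprod(dz, P_[[paste0(sp$id, ".W")]]),
       grads = setNames(list(crossprod(cache$x, dz), colSums(dz)),
                        paste0(sp$id, c(".W", ".b"))))
}

## ---- self-attention ---------------------------------------------------

## Single-head scaled-dot-product self-attention over `tokens` tokens of
## width d. Input rows of length tokens*d are reshaped token-major; output
## is either the flattened token stack ("flatten") or the token mean
## ("mean", used for attention fusion over modality embeddings).
attn_fwd <- function(sp, P_, x) {
  T_ <- sp$tokens; d <- sp$d
  Wq <- P_[[paste0(sp$id, ".Wq")]]; Wk <- P_[[paste0(sp$id, ".Wk")]]
  Wv <- P_[[paste0(sp$id, ".Wv")]]
  N <- nrow(x)
  out <- matrix(0, N, if (sp$out == "flatten") T_ * d else d)
  cc <- vector("list", N)
  for (n in seq_len(N)) {
    X <- matrix(x[n, ], T_, d, byrow = TRUE)
    Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
    S <- tcrossprod(Q, K) / sqrt(d)
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    Y <- A %*% V
    out[n, ] <- if (sp$out == "flatten") as.vector(t(Y)) else colMeans(Y)
    cc[[n]] <- list(X = X, Q = Q, K = K, V = V, A = A)
  }
  list(y = out, cache = cc)
}

attn_bwd <- function(sp, P_, cache, dy) {
  T_ <- sp$tokens; d <- sp$d
  Wq <- P_[[paste0(sp$id, ".Wq")]]; Wk <- P_[[paste0(sp$id, ".Wk")]]
  Wv <- P_[[paste0(sp$id, ".Wv")]]
  N <- nrow(dy)
  dx <- matrix(0, N, T_ * d)
  gWq <- gWk <- gWv <- matrix(0, d, d)
  for (n in seq_len(N)) {
    c_ <- cache[[n]]
    dY <- if (sp$out == "flatten") matrix(dy[n, ], T_, d, byrow = TRUE)
          else matrix(rep(dy[n, ] / T_, each = T_), T_, d)
    dV <- crossprod(c_$A, dY)
    dA <- tcrossprod(dY, c_$V)
    dS <- c_$A * (dA - rowSums(dA * c_$A))
    dQ <- dS %*% c_$K / sqrt(d)
    dK <- crossprod(dS, c_$Q) / sqrt(d)
    dX <- tcrossprod(dQ, Wq) + tcrossprod(dK, Wk) + tcrossprod(dV, Wv)
    gWq <- gWq + crossprod(c_$X, dQ)
    gWk <- gWk + crossprod(c_$X, dK)
    gWv <- gWv + crossprod(c_$X, dV)
    dx[n, ] <- as.vector(t(dX))
  }
  list(dx = dx, grads = setNames(list(gWq, gWk, gWv),
                                 paste0(sp$id, c(".Wq", ".Wk", ".Wv"))))
}

## ---- LSTM -------------------------------------------------------------

## Single-layer LSTM over an (N, T) sequence of scalars; read-out (N, h) is
## either the hidden-state mean over time ("mean", default: every timestep
## receives gradient directly, and the read-out is invariant to the beat
## phase at the segment boundary) or the final-timestep hidden state
## ("last"). Gate order in the stacked weight matrices: input, forget,
## output, candidate.
lstm_fwd <- function(sp, P_, x) {
  f <- lstm_fwd_cpp(P_[[paste0(sp$id, ".Wx")]], P_[[paste0(sp$id, ".Wh")]],
                    P_[[paste0(sp$id, ".b")]], x,
                    !identical(sp$readout, "last"))
  list(y = f$y, cache = c(f[names(f) != "y"], list(x = x)))
}

lstm_bwd <- function(sp, P_, cache, dy) {
  b <- lstm_bwd_cpp(P_[[paste0(sp$id, ".Wx")]], P_[[paste0(sp$id, ".Wh")]],
                    cache$x, dy, cache$I, cache$F, cache$O, cache$G,
                    cache$Cs, cache$Tc, cache$Hs,
                    !identical(sp$readout, "last"))
  list(dx = b$dx,
       grads = setNames(list(b$gWx, b$gWh, as.numeric(b$gb)),
                        paste0(sp$id, c(".Wx", ".Wh", ".b"))))
}

## ---- residual block ---------------------------------------------------

resblock_fwd <- function(sp, P_, S_, x, train) {
  c1 <- spec_conv3(paste0(sp$id, ".c1"), sp$c, sp$c)
  b1 <- spec_bn2d(paste0(sp$id, ".b1"), sp$c)
  c2 <- spec_conv3(paste0(sp$id, ".c2"), sp$c, sp$c)
  b2 <- spec_bn2d(paste0(sp$id, ".b2"), sp$c)
  f1 <- conv3_fwd(c1, P_, x)
  f2 <- bn2d_fwd(b1, P_, S_, f1$y, train)
  f3 <- relu_fwd(f2$y)
  f4 <- conv3_fwd(c2, P_, f3$y)
  f5 <- bn2d_fwd(b2, P_, S_, f4$y, train)
  pre <- f5$y + x
  f6 <- relu_fwd(pre)
  list(y = f6$y,
       cache = list(f1 = f1$cache, f2 = f2$cache, f3 = f3$cache,
                    f4 = f4$cache, f5 = f5$cache, f6 = f6$cache),
       state_updates = c(f2$state_updates, f5$state_updates))
}

resblock_bwd <- function(sp, P_, cache, dy) {
  c1 <- spec_conv3(paste0(sp$id, ".c1"), sp$c, sp$c)
  b1 <- spec_bn2d(paste0(sp$id, ".b1"), sp$c)
  c2 <- spec_conv3(paste0(sp$id, ".c2"), sp$c, sp$c)
  b2 <- spec_bn2d(paste0(sp$id, ".b2"), sp$c)
  r6 <- relu_bwd(cache$f6, dy)
  r5 <- bn2d_bwd(b2, P_, cache$f5, r6$dx)
  r4 <- conv3_bwd(c2, P_, cache$f4, r5$dx)
  r3 <- relu_bwd(cache$f3, r4$dx)
  r2 <- bn2d_bwd(b1, P_, cache$f2, r3$dx)
  r1 <- conv3_bwd(c1, P_, cache$f1, r2$dx)
  list(dx = r1$dx + r6$dx,   # skip path adds the post-residual gradient
       grads = c(r1$grads, r2$grads, r4$grads, r5$grads))
}

## ---- generic dispatch -------------------------------------------------

layer_fwd <- function(sp, P_, S_, x, train) {
  switch(sp$type,
    dense = dense_fwd(sp, P_, x),
    conv3 = conv3_fwd(sp, P_, x),
    bn2d = bn2d_fwd(sp, P_, S_, x, train),
    relu4 = relu_fwd(x),
    maxpool2 = maxpool2_fwd(x),
    gap = gap_fwd(x),
    resblock = resblock_fwd(sp, P_, S_, x, train),
    attn = attn_fwd(sp, P_, x),
    lstm = lstm_fwd(sp, P_, x),
    stop_cadfuse("unknown layer type ", sp$type))
}

layer_bwd <- function(sp, P_, cache, dy) {
  switch(sp$type,
    dense = dense_bwd(sp, P_, cache, dy),
    conv3 = conv3_bwd(sp, P_, cache, dy),
    bn2d = bn2d_bwd(sp, P_, cache, dy),
    relu4 = relu_bwd(cache, dy),
    maxpool2 = maxpool2_bwd(cache, dy),
    gap = gap_bwd(cache, dy),
    resblock = resblock_bwd(sp, P_, cache, dy),
    attn = attn_bwd(sp, P_, cache, dy),
    lstm = lstm_bwd(sp, P_, cache, dy),
    stop_cadfuse("unknown layer type ", sp$type))
}

## sequential stack helpers
stack_init <- function(layers) do.call(c, lapply(layers, layer_init))
stack_state_init <- function(layers) do.call(c, lapply(layers, layer_state_init))

stack_fwd <- function(layers, P_, S_, x, train, keep = TRUE) {
  caches <- if (keep) vector("list", length(layers)) else NULL
  updates <- list()
  for (i in seq_along(layers)) {
    f <- layer_fwd(layers[[i]], P_, S_, x, train)
    x <- f$y
    if (keep) caches[[i]] <- f$cache
    if (!is.null(f$state_updates)) updates <- c(updates, f$state_updates)
  }
  list(y = x, caches = caches, state_updates = updates)
}

## backward through a stack; optionally records the gradient arriving at the
## *input* of each layer (grad_at[[i]] = dL/d input_of_layer_i)
stack_bwd <- function(layers, P_, caches, dy, record = FALSE) {
  grads <- list()
  grad_at <- if (record) vector("list", length(layers)) else NULL
  for (i in rev(seq_along(layers))) {
    b <- layer_bwd(layers[[i]], P_, caches[[i]], dy)
    dy <- b$dx
    if (length(b$grads)) grads <- c(grads, b$grads)
    if (record) grad_at[[i]] <- dy
  }
  list(dx = dy, grads = grads, grad_at = grad_at)
}
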