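# Minimal reverse-mode neural-network primitives used by the sleep stager:
# 1D convolution, ReLU, global average pooling, an LSTM cell, dense layers,
# weighted softmax cross-entropy, and Adam. Everything operates on plain R
# arrays; gradients are exact (checked against finite differences in the
# test suite). Conventions: signals are [batch, length, channels]; conv
# kernels are [k, in, out]; dense weights are [in, out].

nn_rnorm <- function(n, sd) rnorm(n, 0, sd)

he_init <- function(k, cin, cout) {
  array(nn_rnorm(k * cin * cout, sqrt(2 / (k * cin))), dim = c(k, cin, cout))
}

dense_init <- function(cin, cout) {
  matrix(nn_rnorm(cin * cout, sqrt(2 / cin)), cin, cout)
}

# Per-window, per-axis mean removal: strips the quasi-static gravity
# component so later layers see movement, not posture. Jacobian is I - 1/L
# per (window, axis) slice.
center_fwd <- function(x) {
  d <- dim(x)
  for (c in seq_len(d[3])) {
    xc <- matrix(x[, , c], d[1], d[2])
    x[, , c] <- xc - rowMeans(xc)
  }
  list(out = x, cache = d)
}

center_bwd <- function(cache, dout) {
  d <- cache
  for (c in seq_len(d[3])) {
    dc <- matrix(dout[, , c], d[1], d[2])
    dout[, , c] <- dc - rowMeans(dc)
  }
  dout
}

pad_lr <- function(x, p) {
  if (p == 0) {
    return(x)
  }
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2 * p, d[3]))
  xp[, p + seq_len(d[2]), ] <- x
  xp
}

conv1d_fwd <- function(x, W, b, stride = 1, pad = 0) {
  d <- dim(x)
  k <- dim(W)[1]
  cin <- dim(W)[2]
  cout <- dim(W)[3]
  xp <- pad_lr(x, pad)
  lp <- dim(xp)[2]
  lout <- (lp - k) %/% stride + 1
  B <- d[1]
  Y <- matrix(0, B * lout, cout)
  for (t in seq_len(k)) {
    idx <- seq.int(t, by = stride, length.out = lout)
    Xt <- matrix(xp[, idx, ], nrow = B * lout, ncol = cin)
    Y <- Y + Xt %*% matrix(W[t, , ], nrow = cin, ncol = cout)
  }
  Y <- Y + rep(b, each = B * lout)
  list(
    out = array(Y, dim = c(B, lout, cout)),
    cache = list(xp = xp, W = W, stride = stride, pad = pad, in_len = d[2])
  )
}

conv1d_bwd <- function(cache, dout) {
  xp <- cache$xp
  W <- cache$W
  stride <- cache$stride
  pad <- cache$pad
  k <- dim(W)[1]
  cin <- dim(W)[2]
  cout <- dim(W)[3]
  B <- dim(dout)[1]
  lout <- dim(dout)[2]
  M <- matrix(dout, nrow = B * lout, ncol = cout)
  dW <- array(0, dim = dim(W))
  dxp <- array(0, dim = dim(xp))
  for (t in seq_len(k)) {
    idx <- seq.int(t, by = stride, length.out = lout)
    Xt <- matrix(xp[, idx, ], nrow = B * lout, ncol = cin)
    dW[t, , ] <- crossprod(Xt, M)
    dXt <- array(tcrossprod(M, matrix(W[t, , ], nrow = cin, ncol = cout)), dim = c(B, lout, cin))
    dxp[, idx, ] <- dxp[, idx, ] + dXt
  }
  db <- colSums(M)
  dx <- if (pad > 0) dxp[, pad + seq_len(cache$in_len), , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

gap_fwd <- function(x) {
  d <- dim(x)
  out <- matrix(0, d[1], d[3])
  for (c in seq_len(d[3])) out[, c] <- rowMeans(matrix(x[, , c], d[1], d[2]))
  list(out = out, cache = d)
}

gap_bwd <- function(cache, dout) {
  d <- cache
  dx <- array(0, dim = d)
  for (c in seq_len(d[3])) dx[, , c] <- matrix(dout[, c] / d[2], d[1], d[2])
  dx
}

dense_fwd <- function(x, W, b) {
  list(out = x %*% W + rep(b, each = nrow(x)), cache = list(x = x, W = W))
}

dense_bwd <- function(cache, dout) {
  list(
    dx = tcrossprod(dout, cache$W),
    dW = crossprod(cache$x, dout),
    db = colSums(dout)
  )
}

sigm <- function(x) 1 / (1 + exp(-x))

# Sequence-batch normalization over (batch, length) per channel for
# [B, L, C] arrays. Statistics always come from the current batch (one whole
# night, or one SSL minibatch), so training and inference see the same
# transform and inference stays deterministic per sequence.
bn_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  y <- x
  xhat <- x
  mu <- numeric(C)
  v <- numeric(C)
  for (c in seq_len(C)) {
    xc <- matrix(x[, , c], d[1], d[2])
    mu[c] <- mean(xc)
    v[c] <- mean((xc - mu[c])^2)
    xhat[, , c] <- (xc - mu[c]) / sqrt(v[c] + eps)
    y[, , c] <- gamma[c] * xhat[, , c] + beta[c]
  }
  list(out = y, cache = list(xhat = xhat, gamma = gamma, inv_std = 1 / sqrt(v + eps), n = d[1] * d[2]))
}

bn_bwd <- function(cache, dout) {
  xhat <- cache$xhat
  d <- dim(xhat)
  C <- d[3]
  n <- cache$n
  dx <- dout
  dgamma <- numeric(C)
  dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dy <- matrix(dout[, , c], d[1], d[2])
    xh <- matrix(xhat[, , c], d[1], d[2])
    dgamma[c] <- sum(dy * xh)
    dbeta[c] <- sum(dy)
    dx[, , c] <- cache$gamma[c] * cache$inv_std[c] / n *
      (n * dy - dbeta[c] - xh * dgamma[c])
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lstm_init <- function(e, h) {
  list(
    Wx = matrix(nn_rnorm(e * 4 * h, sqrt(1 / e)), e, 4 * h),
    Wh = matrix(nn_rnorm(h * 4 * h, sqrt(1 / h)), h, 4 * h),
    b = {
      b <- rep(0, 4 * h)
      b[(h + 1):(2 * h)] <- 1 # forget-gate bias
      b
    }
  )
}

# One direction over a [T, E] sequence. Gate order i, f, g, o.
lstm_fwd <- function(x, p) {
  Tn <- nrow(x)
  h <- length(p$b) / 4
  Zx <- x %*% p$Wx
  H <- matrix(0, Tn, h)
  C <- matrix(0, Tn, h)
  G <- matrix(0, Tn, 4 * h)
  hprev <- rep(0, h)
  cprev <- rep(0, h)
  ii <- seq_len(h)
  fi <- h + ii
  gi <- 2 * h + ii
  oi <- 3 * h + ii
  for (t in seq_len(Tn)) {
    a <- Zx[t, ] + drop(hprev %*% p$Wh) + p$b
    i_g <- sigm(a[ii])
    f_g <- sigm(a[fi])
    g_g <- tanh(a[gi])
    o_g <- sigm(a[oi])
    cprev <- f_g * cprev + i_g * g_g
    hprev <- o_g * tanh(cprev)
    G[t, ] <- c(i_g, f_g, g_g, o_g)
    C[t, ] <- cprev
    H[t, ] <- hprev
  }
  list(out = H, cache = list(x = x, G = G, C = C, H = H, p = p))
}

lstm_bwd <- function(cache, dH) {
  x <- cache$x
  G <- cache$G
  C <- cache$C
  H <- cache$H
  p <- cache$p
  Tn <- nrow(x)
  h <- ncol(H)
  ii <- seq_len(h)
  fi <- h + ii
  gi <- 2 * h + ii
  oi <- 3 * h + ii
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dWh <- matrix(0, h, 4 * h)
  db <- rep(0, 4 * h)
  dx <- matrix(0, Tn, ncol(x))
  dh_next <- rep(0, h)
  dc_next <- rep(0, h)
  for (t in rev(seq_len(Tn))) {
    i_g <- G[t, ii]
    f_g <- G[t, fi]
    g_g <- G[t, gi]
    o_g <- G[t, oi]
    c_t <- C[t, ]
    c_prev <- if (t > 1) C[t - 1, ] else rep(0, h)
    h_prev <- if (t > 1) H[t - 1, ] else rep(0, h)
    dh <- dH[t, ] + dh_next
    tc <- tanh(c_t)
    do_g <- dh * tc
    dc <- dh * o_g * (1 - tc^2) + dc_next
    di <- dc * g_g
    df <- dc * c_prev
    dg <- dc * i_g
    dc_next <- dc * f_g
    da <- c(
      di * i_g * (1 - i_g),
      df * f_g * (1 - f_g),
      dg * (1 - g_g^2),
      do_g * o_g * (1 - o_g)
    )
    dWx <- dWx + outer(x[t, ], da)
    dWh <- dWh + outer(h_prev, da)
    db <- db + da
    dx[t, ] <- drop(p$Wx %*% da)
    dh_next <- drop(p$Wh %*% da)
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Class-weighted cross-entropy over rows of `logits`; `y` integer labels,
# `mask` logical rows to include. Returns mean weighted loss and dlogits.
wce_fwd_bwd <- function(logits, y, class_w, mask = NULL) {
  n <- nrow(logits)
  if (is.null(mask)) mask <- rep(TRUE, n)
  p <- softmax_rows(logits)
  w <- class_w[y] * mask
  norm <- sum(w)
  if (norm == 0) {
    return(list(loss = 0, dlogits = matrix(0, n, ncol(logits)), probs = p))
  }
  picked <- p[cbind(seq_len(n), y)]
  loss <- -sum(w * log(pmax(picked, 1e-12))) / norm
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  dlogits <- dlogits * (w / norm)
  list(loss = loss, dlogits = dlogits, probs = p)
}

adam_new <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0
  )
}

adam_step <- function(params, grads, state, lr = 3e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

grad_accum <- function(acc, g) {
  if (is.null(acc)) {
    return(g)
  }
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}
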