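## Network building blocks.
##
## All activations are H x W x C arrays (batch of one; minibatches loop).
## Convolutions are computed as sums of shifted-slice matrix products so the
## heavy lifting lands in BLAS. Each *_forward returns the output plus the
## cache its *_backward needs.

mat3 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

unmat3 <- function(x, H, W) {
  dim(x) <- c(H, W, ncol(x))
  x
}

wslice <- function(W, di, dj) {
  d <- dim(W)
  matrix(W[di, dj, , ], d[3], d[4])
}

## ---- zero-padded same-size convolution ----

conv_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  kh <- dim(W)[1]; Cout <- dim(W)[4]
  if (kh == 1L) {
    out <- mat3(x) %*% wslice(W, 1, 1)
    out <- out + rep(b, each = nrow(out))
    return(list(out = unmat3(out, H, Wd), x = x))
  }
  p <- (kh - 1L) %/% 2L
  xp <- array(0, c(H + 2L * p, Wd + 2L * p, Cin))
  xp[p + seq_len(H), p + seq_len(Wd), ] <- x
  out <- matrix(0, H * Wd, Cout)
  for (di in seq_len(kh)) {
    for (dj in seq_len(kh)) {
      xs <- xp[di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE]
      out <- out + mat3(xs) %*% wslice(W, di, dj)
    }
  }
  out <- out + rep(b, each = nrow(out))
  list(out = unmat3(out, H, Wd), xp = xp, H = H, W = Wd)
}

conv_backward <- function(dout, cache, W) {
  kh <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  dm <- mat3(dout)
  db <- colSums(dm)
  dW <- array(0, dim(W))
  if (kh == 1L) {
    x <- cache$x
    dW[1, 1, , ] <- crossprod(mat3(x), dm)
    dx <- unmat3(dm %*% t(wslice(W, 1, 1)), dim(x)[1], dim(x)[2])
    return(list(dx = dx, dW = dW, db = db))
  }
  xp <- cache$xp; H <- cache$H; Wd <- cache$W
  p <- (kh - 1L) %/% 2L
  dxp <- array(0, dim(xp))
  for (di in seq_len(kh)) {
    for (dj in seq_len(kh)) {
      xs <- xp[di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE]
      dW[di, dj, , ] <- crossprod(mat3(xs), dm)
      dxs <- unmat3(dm %*% t(wslice(W, di, dj)), H, Wd)
      dxp[di:(di + H - 1L), dj:(dj + Wd - 1L), ] <-
        dxp[di:(di + H - 1L), dj:(dj + Wd - 1L), , drop = FALSE] + dxs
    }
  }
  list(dx = dxp[p + seq_len(H), p + seq_len(Wd), , drop = FALSE],
       dW = dW, db = db)
}

## ---- batch normalization (statistics over the spatial extent) ----

bn_forward <- function(x, gamma, beta, rstate, training,
                       momentum = 0.9, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- mat3(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc^2)
    rstate$mean <- momentum * rstate$mean + (1 - momentum) * mu
    rstate$var <- momentum * rstate$var + (1 - momentum) * v
  } else {
    mu <- rstate$mean
    v <- rstate$var
    xc <- xm - rep(mu, each = n)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = n)
  y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = unmat3(y, d[1], d[2]), rstate = rstate,
       xhat = xhat, inv = inv, n = n, H = d[1], W = d[2])
}

bn_backward <- function(dout, cache, gamma) {
  n <- cache$n
  dy <- mat3(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
    rep(cache$inv, each = n)
  list(dx = unmat3(dx, cache$H, cache$W), dgamma = dgamma, dbeta = dbeta)
}

## ---- ReLU ----

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_backward <- function(dout, cache) dout * cache$mask

## ---- 2x2 stride-2 max pooling ----

pool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  r1 <- seq(1L, H, 2L); r2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W, 2L); c2 <- seq(2L, W, 2L)
  x11 <- x[r1, c1, , drop = FALSE]; x12 <- x[r1, c2, , drop = FALSE]
  x21 <- x[r2, c1, , drop = FALSE]; x22 <- x[r2, c2, , drop = FALSE]
  out <- pmax(x11, x12, x21, x22)
  ## deterministic tie-break: first window position in (11, 12, 21, 22) order
  arg <- array(4L, dim(out))
  arg[x21 == out] <- 3L
  arg[x12 == out] <- 2L
  arg[x11 == out] <- 1L
  list(out = out, arg = arg, H = H, W = W)
}

pool_backward <- function(dout, cache) {
  H <- cache$H; W <- cache$W
  dx <- array(0, c(H, W, dim(dout)[3]))
  r1 <- seq(1L, H, 2L); r2 <- seq(2L, H, 2L)
  c1 <- seq(1L, W, 2L); c2 <- seq(2L, W, 2L)
  arg <- cache$arg
  dx[r1, c1, ] <- dout * (arg == 1L)
  dx[r1, c2, ] <- dout * (arg == 2L)
  dx[r2, c1, ] <- dout * (arg == 3L)
  dx[r2, c2, ] <- dout * (arg == 4L)
  dx
}

## ---- 2x2 stride-2 transposed convolution (up-sampling) ----

deconv_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]
  Cout <- dim(W)[4]
  out <- array(0, c(2L * H, 2L * Wd, Cout))
  xm <- mat3(x)
  for (di in 1:2) {
    for (dj in 1:2) {
      out[seq(di, 2L * H, 2L), seq(dj, 2L * Wd, 2L), ] <-
        unmat3(xm %*% wslice(W, di, dj), H, Wd)
    }
  }
  out <- out + rep(b, each = 4L * H * Wd)
  list(out = out, x = x)
}

deconv_backward <- function(dout, cache, W) {
  x <- cache$x
  d <- dim(x); H <- d[1]; Wd <- d[2]
  dW <- array(0, dim(W))
  db <- colSums(mat3(dout))
  dx <- matrix(0, H * Wd, d[3])
  xm <- mat3(x)
  for (di in 1:2) {
    for (dj in 1:2) {
      ds <- mat3(dout[seq(di, 2L * H, 2L), seq(dj, 2L * Wd, 2L), ,
                      drop = FALSE])
      dW[di, dj, , ] <- crossprod(xm, ds)
      dx <- dx + ds %*% t(wslice(W, di, dj))
    }
  }
  list(dx = unmat3(dx, H, Wd), dW = dW, db = db)
}

## ---- composite Conv block: convolution + BN + ReLU ----

convblock_forward <- function(x, p, rstate, training) {
  cv <- conv_forward(x, p$W, p$b)
  bn <- bn_forward(cv$out, p$gamma, p$beta, rstate, training)
  rl <- relu_forward(bn$out)
  list(out = rl$out, rstate = bn$rstate,
       cache = list(conv = cv, bn = bn, relu = rl))
}

convblock_backward <- function(dout, cache, p) {
  dr <- relu_backward(dout, cache$relu)
  dbn <- bn_backward(dr, cache$bn, p$gamma)
  dcv <- conv_backward(dbn$dx, cache$conv, p$W)
  list(dx = dcv$dx,
       grads = list(W = dcv$dW, b = dcv$db,
                    gamma = dbn$dgamma, beta = dbn$dbeta))
}
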