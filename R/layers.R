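# Internal NN layer primitives. Activations are [H, W, C, N] arrays,
# kernels [kh, kw, Cin, Cout]. Conv and 2x2 average pooling run in compiled
# code; batch norm, ReLU and the linear head are vectorized R.

convFw <- function(x, w, b, stride = 1L, pad = 0L) {
  xd <- dim(x)
  wd <- dim(w)
  ho <- (xd[1] + 2L * pad - wd[1]) %/% stride + 1L
  wo <- (xd[2] + 2L * pad - wd[2]) %/% stride + 1L
  X2 <- im2col_cpp(x, xd, wd[1], wd[2], as.integer(stride), as.integer(pad))
  Y2 <- X2 %*% matrix(w, wd[1] * wd[2] * wd[3], wd[4])
  Y2 <- Y2 + rep(b, each = nrow(Y2))
  aperm(array(Y2, c(ho, wo, xd[4], wd[4])), c(1, 2, 4, 3))
}

convBw <- function(x, w, gy, stride = 1L, pad = 0L) {
  xd <- dim(x)
  wd <- dim(w)
  gyd <- dim(gy)
  X2 <- im2col_cpp(x, xd, wd[1], wd[2], as.integer(stride), as.integer(pad))
  gy2 <- matrix(aperm(gy, c(1, 2, 4, 3)), gyd[1] * gyd[2] * gyd[4], gyd[3])
  gw <- array(crossprod(X2, gy2), dim = wd)
  gb <- colSums(gy2)
  gcols <- tcrossprod(gy2, matrix(w, wd[1] * wd[2] * wd[3], wd[4]))
  gx <- col2im_cpp(gcols, xd, wd[1], wd[2], as.integer(stride),
                   as.integer(pad))
  list(gx = gx, gw = gw, gb = gb)
}

poolFw <- function(x) avgpool2_fw_cpp(x, dim(x))

poolBw <- function(gy, xdim) avgpool2_bw_cpp(gy, dim(gy), as.integer(xdim))

bnFw <- function(x, gamma, beta, rmean, rvar, training, momentum = 0.1,
                 eps = 1e-5) {
  d <- dim(x)
  M <- d[1] * d[2] * d[4]
  C <- d[3]
  xp <- matrix(aperm(x, c(1, 2, 4, 3)), M, C)
  if (training) {
    mu <- colMeans(xp)
    v <- pmax(colMeans(xp * xp) - mu * mu, 0)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (xp - rep(mu, each = M)) * rep(invstd, each = M)
  y <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  ya <- aperm(array(y, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(y = ya, rmean = rmean, rvar = rvar,
       cache = list(xhat = xhat, invstd = invstd, d = d, training = training))
}

bnBw <- function(dy, gamma, cache) {
  d <- cache$d
  M <- d[1] * d[2] * d[4]
  C <- d[3]
  dyp <- matrix(aperm(dy, c(1, 2, 4, 3)), M, C)
  xhat <- cache$xhat
  dgamma <- colSums(dyp * xhat)
  dbeta <- colSums(dyp)
  dxhat <- dyp * rep(gamma, each = M)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- rep(cache$invstd / M, each = M) *
      (M * dxhat - rep(s1, each = M) - xhat * rep(s2, each = M))
  } else {
    dx <- dxhat * rep(cache$invstd, each = M)
  }
  dxa <- aperm(array(dx, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  list(dx = dxa, dgamma = dgamma, dbeta = dbeta)
}

reluFw <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

reluBw <- function(dy, x) dy * (x > 0)

catChannels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

globalPoolFw <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
}

globalPoolBw <- function(gf, xdim) {
  # gf is C x N; spread gradient uniformly over H*W positions
  scale <- 1 / (xdim[1] * xdim[2])
  g <- array(rep(as.vector(gf), each = xdim[1] * xdim[2]), dim = xdim)
  g * scale
}

softmaxProbs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Mean cross-entropy and its logits gradient for integer targets (1-based).
softmaxCrossEntropy <- function(logits, targets) {
  n <- ncol(logits)
  p <- softmaxProbs(logits)
  idx <- cbind(targets, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, dlogits = g / n, probs = p)
}
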