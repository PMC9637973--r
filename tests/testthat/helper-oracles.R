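# Scalar double-loop oracles for the attention blocks, written independently
# of the vectorized implementation: every attention weight is computed one
# scalar at a time. Shared across unit and acceptance tests.

oracle_conv1x1 <- function(x, W, b) {
  cin <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  cout <- dim(W)[1]
  out <- array(0, c(cout, h, w))
  for (o in seq_len(cout)) {
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        s <- b[o]
        for (ci in seq_len(cin)) s <- s + W[o, ci, 1, 1] * x[ci, i, j]
        out[o, i, j] <- s
      }
    }
  }
  out
}

# flatten (c, h, w) -> c x hw, position index p = (j - 1) * h + i
oracle_flat <- function(x) {
  c <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  m <- matrix(0, c, h * w)
  for (i in seq_len(h)) for (j in seq_len(w)) m[, (j - 1) * h + i] <- x[, i, j]
  m
}

oracle_row_softmax <- function(m) {
  out <- m
  for (i in seq_len(nrow(m))) {
    r <- m[i, ] - max(m[i, ])
    e <- exp(r)
    out[i, ] <- e / sum(e)
  }
  out
}

oracle_spatial_ggb <- function(fx, fg, w) {
  a <- oracle_flat(oracle_conv1x1(fx, w[["ggb_s.alpha.W"]], w[["ggb_s.alpha.b"]]))
  b <- oracle_flat(oracle_conv1x1(fx, w[["ggb_s.beta.W"]], w[["ggb_s.beta.b"]]))
  g <- oracle_flat(oracle_conv1x1(fx, w[["ggb_s.gamma.W"]], w[["ggb_s.gamma.b"]]))
  e <- oracle_flat(oracle_conv1x1(fg, w[["ggb_s.eta.W"]], w[["ggb_s.eta.b"]]))
  r <- oracle_flat(oracle_conv1x1(fg, w[["ggb_s.rho.W"]], w[["ggb_s.rho.b"]]))
  hw <- ncol(a)
  sw <- matrix(0, hw, hw)
  mg <- matrix(0, hw, hw)
  for (i in seq_len(hw)) {
    for (j in seq_len(hw)) {
      sw[i, j] <- sum(a[, i] * b[, j])
      mg[i, j] <- sum(e[, i] * r[, j])
    }
  }
  sw <- oracle_row_softmax(sw)
  mg <- oracle_row_softmax(mg)
  ms <- oracle_row_softmax(sw * mg)
  d <- dim(fx)
  y <- fx
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      p <- (j - 1) * d[2] + i
      acc <- numeric(d[1])
      for (q in seq_len(hw)) acc <- acc + ms[p, q] * g[, q]
      y[, i, j] <- fx[, i, j] + acc
    }
  }
  list(y = y, SW = sw, MG = mg, MS = ms)
}

oracle_se <- function(fg, w) {
  cc <- dim(fg)[1]; h <- dim(fg)[2]; ww <- dim(fg)[3]
  lam <- numeric(cc)
  for (k in seq_len(cc)) {
    s <- 0
    for (i in seq_len(h)) for (j in seq_len(ww)) s <- s + fg[k, i, j]
    lam[k] <- s / (h * ww)
  }
  hid <- pmax(as.vector(w[["se.P1"]] %*% lam + w[["se.b1"]]), 0)
  vc <- 1 / (1 + exp(-(as.vector(w[["se.P2"]] %*% hid + w[["se.b2"]]))))
  fghat <- fg
  for (k in seq_len(cc)) fghat[k, , ] <- fg[k, , ] * vc[k]
  list(lambda = lam, vc = vc, map = fghat)
}

oracle_channel_ggb <- function(y, fg, w) {
  yf <- oracle_flat(y)
  se <- oracle_se(fg, w)
  gf <- oracle_flat(se$map)
  cc <- nrow(yf)
  mz <- matrix(0, cc, cc)
  mghat <- matrix(0, cc, cc)
  for (k in seq_len(cc)) {
    for (l in seq_len(cc)) {
      mz[k, l] <- sum(yf[k, ] * yf[l, ])
      mghat[k, l] <- sum(gf[k, ] * gf[l, ])
    }
  }
  mz <- oracle_row_softmax(mz)
  mghat <- oracle_row_softmax(mghat)
  mq <- oracle_row_softmax(mz * mghat)
  fz <- matrix(0, cc, ncol(yf))
  for (k in seq_len(cc)) {
    for (p in seq_len(ncol(yf))) fz[k, p] <- sum(mq[k, ] * yf[, p])
  }
  d <- dim(y)
  z <- y
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      z[, i, j] <- y[, i, j] + fz[, (j - 1) * d[2] + i]
    }
  }
  list(z = z, MZ = mz, MG_hat = mghat, MQ = mq)
}

# small random feature arrays under a fixed seed
rand_feat <- function(c, h, w, seed) {
  set.seed(seed)
  array(stats::rnorm(c * h * w), c(c, h, w))
}

tiny_test_config <- function(...) tiny_model_config(...)
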