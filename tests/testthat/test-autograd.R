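# The autodiff core is validated against central finite differences: if
# these pass, every analytic backward rule in the engine is consistent with
# its forward computation.

num_grad <- function(fn, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(2 * 5 * 6 * 2), c(2, 5, 6, 2))
  W <- array(rnorm(3 * 2 * 3 * 3) * 0.3, c(3, 2, 3, 3))
  b <- rnorm(3)
  run <- function(xv, Wv, bv) {
    xn <- ugbnet:::ag_tensor(xv, TRUE); Wn <- ugbnet:::ag_tensor(Wv, TRUE); bn <- ugbnet:::ag_tensor(bv, TRUE)
    out <- ugbnet:::ag_relu(ugbnet:::ag_conv2d(xn, Wn, bn, stride = 2L))
    list(l = ugbnet:::ag_bce_logits(out, array(0.3, dim(out$value))),
         xn = xn, Wn = Wn, bn = bn)
  }
  r <- run(x, W, b)
  ugbnet:::ag_backward(r$l)
  f <- function(make) function(v) ugbnet:::ag_no_grad(make(v)$l$value)
  expect_lt(max(abs(r$xn$grad - num_grad(f(function(v) run(v, W, b)), x))), 1e-6)
  expect_lt(max(abs(r$Wn$grad - num_grad(f(function(v) run(x, v, b)), W))), 1e-6)
  expect_lt(max(abs(r$bn$grad - num_grad(f(function(v) run(x, W, v)), b))), 1e-6)
})

test_that("attention-style op chain gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(3 * 4 * 4 * 2), c(3, 4, 4, 2))
  W <- array(rnorm(3 * 3 * 3 * 3) * 0.3, c(3, 3, 3, 3))
  run <- function(xv, Wv) {
    xn <- ugbnet:::ag_tensor(xv, TRUE); Wn <- ugbnet:::ag_tensor(Wv, TRUE)
    h <- ugbnet:::ag_conv2d(xn, Wn, NULL, dilation = 1L)
    h <- ugbnet:::ag_resize_bilinear(h, 6L, 6L)
    lam <- ugbnet:::ag_gap(h)
    v <- ugbnet:::ag_sigmoid(ugbnet:::ag_linear(
      ugbnet:::ag_relu(ugbnet:::ag_linear(lam, ugbnet:::ag_tensor(matrix(0.5, 2, 3)))),
      ugbnet:::ag_tensor(matrix(0.4, 3, 2))))
    h2 <- ugbnet:::ag_channel_scale(h, v)
    f <- ugbnet:::ag_reshape(h2, c(3, 36, 2))
    S <- ugbnet:::ag_softmax_rows(ugbnet:::ag_bmm(f, f, tb = TRUE))
    z <- ugbnet:::ag_bmm(S, f)
    list(l = ugbnet:::ag_bce_logits(z, array(0.7, dim(z$value))), xn = xn, Wn = Wn)
  }
  r <- run(x, W)
  ugbnet:::ag_backward(r$l)
  f <- function(make) function(v) ugbnet:::ag_no_grad(make(v)$l$value)
  expect_lt(max(abs(r$xn$grad - num_grad(f(function(v) run(v, W)), x))), 1e-6)
  expect_lt(max(abs(r$Wn$grad - num_grad(f(function(v) run(x, v)), W))), 1e-6)
})

test_that("dilated convolution enlarges the gradient support on the input", {
  # receptive-field probe: backpropagate from one output pixel and measure
  # the nonzero region on the input
  probe <- function(dilation) {
    x <- ugbnet:::ag_tensor(array(0, c(1, 15, 15, 1)), TRUE)
    W <- ugbnet:::ag_tensor(array(1, c(1, 1, 3, 3)))
    out <- ugbnet:::ag_conv2d(x, W, NULL, dilation = dilation)
    g <- array(0, dim(out$value)); g[1, 8, 8, 1] <- 1
    ugbnet:::ag_backward(out, g)
    which(x$grad[1, , 8, 1] != 0)
  }
  expect_equal(probe(1L), 7:9)
  expect_equal(probe(3L), c(5, 8, 11))
})
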