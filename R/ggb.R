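# Global guidance blocks: the spatial-wise and channel-wise attention
# modules that refine the DASPP output FX under the multi-scale guidance
# map FG.
#
# Flattening convention: a (c, h, w) feature map flattens to a c x (hw)
# matrix column-major (depth index fastest), the natural order for R arrays.
# Every similarity matrix is row-stochastic: each query row is a softmax
# over keys.

# flatten (c, h, w, n) -> (c, hw, n)
flat_sp <- function(x) {
  d <- dim(x$value)
  ag_reshape(x, c(d[1], d[2] * d[3], d[4]))
}

nn_spatial_ggb <- function(fx, fg, weights, collect = FALSE) {
  d <- dim(fx$value)
  if (!identical(d, dim(fg$value))) stop("fx and fg shapes differ")
  alpha <- flat_sp(conv_block(fx, weights, "ggb_s.alpha", act = FALSE))
  beta  <- flat_sp(conv_block(fx, weights, "ggb_s.beta",  act = FALSE))
  gam   <- flat_sp(conv_block(fx, weights, "ggb_s.gamma", act = FALSE))
  eta   <- flat_sp(conv_block(fg, weights, "ggb_s.eta",   act = FALSE))
  rho   <- flat_sp(conv_block(fg, weights, "ggb_s.rho",   act = FALSE))
  # SW[i, j] = softmax_j <alpha_i, beta_j>  (hw x hw)
  sw <- ag_softmax_rows(ag_bmm(alpha, beta, ta = TRUE))
  mg <- ag_softmax_rows(ag_bmm(eta, rho, ta = TRUE))
  ms <- ag_softmax_rows(ag_mul(sw, mg))
  # FY = MS %*% t(gamma-flat) : (hw x c), then back to (c, h, w)
  fy <- ag_bmm(ms, gam, tb = TRUE)
  y_flat <- ag_op(aperm(fy$value, c(2, 1, 3)), list(fy),
                  function(g) list(aperm(g, c(2, 1, 3))))
  y <- ag_add(ag_reshape(y_flat, d), fx)
  if (collect) list(y = y, sims = list(SW = sw$value, MG = mg$value, MS = ms$value))
  else list(y = y)
}

nn_squeeze_excite <- function(fg, weights) {
  lam <- ag_gap(fg)                     # (c, n) channel statistics
  hid <- ag_relu(ag_linear(lam, wparam(weights, "se.P1"), wparam(weights, "se.b1")))
  vc <- ag_sigmoid(ag_linear(hid, wparam(weights, "se.P2"), wparam(weights, "se.b2")))
  list(map = ag_channel_scale(fg, vc), lambda = lam, vc = vc)
}

nn_channel_ggb <- function(y, fg, weights, collect = FALSE) {
  d <- dim(y$value)
  if (!identical(d, dim(fg$value))) stop("y and fg shapes differ")
  yf <- flat_sp(y)                      # (c, hw, n)
  mz <- ag_softmax_rows(ag_bmm(yf, yf, tb = TRUE))        # (c, c, n)
  se <- nn_squeeze_excite(fg, weights)
  gf <- flat_sp(se$map)
  mghat <- ag_softmax_rows(ag_bmm(gf, gf, tb = TRUE))
  mq <- ag_softmax_rows(ag_mul(mz, mghat))
  fz <- ag_bmm(mq, yf)                  # (c, hw, n)
  z <- ag_add(ag_reshape(fz, d), y)
  out <- list(z = z, lambda = se$lambda, vc = se$vc)
  if (collect) out$sims <- list(MZ = mz$value, MG_hat = mghat$value, MQ = mq$value)
  out
}

#' Spatial-wise global guidance block
#'
#' Non-local spatial attention over the feature map `fx`, steered by the
#' guidance map `fg`. Three 1x1 convolutions produce query/key/value maps
#' from `fx`; the query-key similarity softmax gives the hw x hw
#' position-similarity matrix `SW`. Two further 1x1 convolutions on `fg`
#' give the guidance similarity `MG` the same way. Their elementwise product,
#' re-normalized by a row softmax, is the guided similarity `MS`, which
#' aggregates the value map; a residual connection adds `fx` back.
#'
#' @param fx (c, h, w) or (c, h, w, n) feature array (DASPP output).
#' @param fg guidance array of identical shape.
#' @param weights from [init_ugbnet()].
#' @param collect_sims also return the similarity matrices (for diagnostics).
#' @return the refined map `Y` (same shape as `fx`); with
#'   `collect_sims = TRUE`, a list with elements `y` and `sims`
#'   (`SW`, `MG`, `MS`, each (hw, hw, n) row-stochastic).
#' @export
spatial_ggb <- function(fx, fg, weights, collect_sims = FALSE) {
  x <- as_chwn(fx); g <- as_chwn(fg)
  ag_no_grad(res <- nn_spatial_ggb(ag_tensor(x), ag_tensor(g), weights,
                                   collect = collect_sims))
  y <- res$y$value
  if (is.matrix(fx) || length(dim(fx)) == 3L) y <- array(y, dim(y)[1:3])
  if (collect_sims) list(y = y, sims = res$sims) else y
}

#' Squeeze-and-excitation channel gate
#'
#' Global average pooling of `fg` gives the channel statistics `lambda`; two
#' fully connected layers with a ReLU between them and a sigmoid on top give
#' the per-channel coefficients `vc` in (0, 1), which rescale the channels
#' of `fg`.
#'
#' @param fg (c, h, w) or (c, h, w, n) guidance array.
#' @param weights from [init_ugbnet()] (uses `se.P1`, `se.b1`, `se.P2`,
#'   `se.b2`).
#' @return list with `map` (rescaled `fg`), `lambda` (c x n) and `vc`
#'   (c x n).
#' @export
squeeze_excite <- function(fg, weights) {
  g <- as_chwn(fg)
  ag_no_grad(res <- nn_squeeze_excite(ag_tensor(g), weights))
  m <- res$map$value
  if (is.matrix(fg) || length(dim(fg)) == 3L) m <- array(m, dim(m)[1:3])
  list(map = m, lambda = res$lambda$value, vc = res$vc$value)
}

#' Channel-wise global guidance block
#'
#' Channel attention over `y` guided by `fg`: the c x c channel similarity
#' `MZ` comes from `y` against itself; the squeeze-and-excitation-refined
#' guidance gives `MG_hat` the same way; their elementwise product,
#' re-normalized row-wise, is the guided similarity `MQ` that mixes the
#' channels of `y`; a residual connection adds `y` back.
#'
#' @param y (c, h, w) or (c, h, w, n) feature array (spatial block output).
#' @param fg guidance array of identical shape.
#' @inheritParams spatial_ggb
#' @return the refined map `Z`; with `collect_sims = TRUE`, a list with `z`
#'   and `sims` (`MZ`, `MG_hat`, `MQ`, each (c, c, n) row-stochastic).
#' @export
channel_ggb <- function(y, fg, weights, collect_sims = FALSE) {
  yv <- as_chwn(y); g <- as_chwn(fg)
  ag_no_grad(res <- nn_channel_ggb(ag_tensor(yv), ag_tensor(g), weights,
                                   collect = collect_sims))
  z <- res$z$value
  if (is.matrix(y) || length(dim(y)) == 3L) z <- array(z, dim(z)[1:3])
  if (collect_sims) list(z = z, sims = res$sims) else z
}
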