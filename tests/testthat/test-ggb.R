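# The attention blocks are checked against scalar double-loop oracles
# (helper-oracles.R) that compute every attention weight one scalar at a
# time, plus the degenerate closed forms.

ggb_weights <- function(seed = 4, c = 4) {
  init_ugbnet(tiny_model_config(attention_channels = c, se_reduction = 2),
              seed = seed)
}

test_that("spatial block matches the scalar oracle on random inputs", {
  for (seed in 1:3) {
    w <- ggb_weights(seed)
    fx <- rand_feat(4, 3, 3, seed + 10)
    fg <- rand_feat(4, 3, 3, seed + 20)
    got <- spatial_ggb(fx, fg, w, collect_sims = TRUE)
    want <- oracle_spatial_ggb(fx, fg, w)
    expect_lt(max(abs(got$y - want$y)) / max(abs(want$y)), 1e-5)
    expect_lt(max(abs(got$sims$SW[, , 1] - want$SW)), 1e-5)
    expect_lt(max(abs(got$sims$MG[, , 1] - want$MG)), 1e-5)
    expect_lt(max(abs(got$sims$MS[, , 1] - want$MS)), 1e-5)
  }
})

test_that("channel block matches the scalar oracle on random inputs", {
  for (seed in 1:3) {
    w <- ggb_weights(seed)
    y <- rand_feat(4, 3, 3, seed + 30)
    fg <- rand_feat(4, 3, 3, seed + 40)
    got <- channel_ggb(y, fg, w, collect_sims = TRUE)
    want <- oracle_channel_ggb(y, fg, w)
    expect_lt(max(abs(got$z - want$z)) / max(abs(want$z)), 1e-5)
    expect_lt(max(abs(got$sims$MZ[, , 1] - want$MZ)), 1e-5)
    expect_lt(max(abs(got$sims$MG_hat[, , 1] - want$MG_hat)), 1e-5)
    expect_lt(max(abs(got$sims$MQ[, , 1] - want$MQ)), 1e-5)
  }
})

test_that("single-position spatial block reduces to gamma(fx) + fx", {
  w <- ggb_weights(1)
  fx <- rand_feat(4, 1, 1, 2)
  fg <- rand_feat(4, 1, 1, 3)
  got <- spatial_ggb(fx, fg, w, collect_sims = TRUE)
  gam <- oracle_conv1x1(fx, w[["ggb_s.gamma.W"]], w[["ggb_s.gamma.b"]])
  expect_equal(got$y, fx + gam, tolerance = 1e-12)
  for (s in got$sims) expect_equal(as.vector(s), 1)
})

test_that("constant guidance makes MG uniform and MS a renormalized SW", {
  w <- ggb_weights(2)
  fx <- rand_feat(4, 3, 3, 5)
  fg <- array(0.7, c(4, 3, 3))
  got <- spatial_ggb(fx, fg, w, collect_sims = TRUE)
  expect_equal(max(abs(got$sims$MG[, , 1] - 1 / 9)), 0, tolerance = 1e-12)
  sw <- got$sims$SW[, , 1]
  renorm <- oracle_row_softmax(sw / 9)
  expect_equal(got$sims$MS[, , 1], renorm, tolerance = 1e-10)
})

test_that("single-channel channel block doubles its input", {
  w <- init_ugbnet(tiny_model_config(attention_channels = 1, se_reduction = 1),
                   seed = 3)
  y <- rand_feat(1, 3, 4, 6)
  fg <- rand_feat(1, 3, 4, 7)
  expect_equal(channel_ggb(y, fg, w), 2 * y, tolerance = 1e-12)
})

test_that("zero y annihilates the channel block output", {
  w <- ggb_weights(3)
  z <- channel_ggb(array(0, c(4, 3, 3)), rand_feat(4, 3, 3, 8), w)
  expect_true(all(z == 0))
})

test_that("squeeze-excite statistics match the double-loop oracle", {
  w <- ggb_weights(5)
  fg <- rand_feat(4, 5, 6, 9)
  fg[2, , ] <- 2.0
  got <- squeeze_excite(fg, w)
  want <- oracle_se(fg, w)
  expect_equal(as.vector(got$lambda), want$lambda, tolerance = 1e-12)
  expect_equal(got$lambda[2, 1], 2.0)
  expect_equal(as.vector(got$vc), want$vc, tolerance = 1e-12)
  expect_equal(got$map, want$map, tolerance = 1e-12)
  expect_true(all(got$vc > 0 & got$vc < 1))
})

test_that("zeroed fully connected layers give a half-gate", {
  w <- ggb_weights(6)
  w[["se.P1"]][] <- 0; w[["se.b1"]][] <- 0
  w[["se.P2"]][] <- 0; w[["se.b2"]][] <- 0
  fg <- rand_feat(4, 3, 3, 10)
  got <- squeeze_excite(fg, w)
  expect_equal(as.vector(got$vc), rep(0.5, 4))
  expect_equal(got$map, 0.5 * fg, tolerance = 1e-12)
})

test_that("zeroing the value convolution makes the spatial block an identity", {
  w <- ggb_weights(7)
  w[["ggb_s.gamma.W"]][] <- 0; w[["ggb_s.gamma.b"]][] <- 0
  fx <- rand_feat(4, 3, 3, 11)
  expect_equal(spatial_ggb(fx, rand_feat(4, 3, 3, 12), w), fx, tolerance = 1e-12)
})

test_that("every similarity matrix is row-stochastic across random passes", {
  for (seed in 1:10) {
    w <- ggb_weights(seed)
    fx <- rand_feat(4, 3, 3, 100 + seed)
    fg <- rand_feat(4, 3, 3, 200 + seed)
    s1 <- spatial_ggb(fx, fg, w, collect_sims = TRUE)$sims
    s2 <- channel_ggb(fx, fg, w, collect_sims = TRUE)$sims
    for (m in c(s1, s2)) {
      expect_gte(min(m), 0)
      expect_lt(max(abs(apply(m, 3, rowSums) - 1)), 1e-5)
    }
  }
})

test_that("spatial block is equivariant to spatial permutations", {
  w <- ggb_weights(8)
  fx <- rand_feat(4, 2, 3, 13)
  fg <- rand_feat(4, 2, 3, 14)
  # positions flatten column-major; permute via the flattened index
  perm <- c(4, 1, 6, 2, 5, 3)
  permute_sp <- function(x) {
    m <- oracle_flat(x)[, perm]
    array(m, dim(x))
  }
  y1 <- spatial_ggb(permute_sp(fx), permute_sp(fg), w)
  y2 <- permute_sp(spatial_ggb(fx, fg, w))
  expect_equal(y1, y2, tolerance = 1e-10)
})

test_that("channel block is equivariant to channel permutations", {
  w <- ggb_weights(9)
  y <- rand_feat(4, 3, 3, 15)
  fg <- rand_feat(4, 3, 3, 16)
  perm <- c(3, 1, 4, 2)
  wp <- w
  wp[["se.P1"]] <- w[["se.P1"]][, perm]
  wp[["se.P2"]] <- w[["se.P2"]][perm, ]
  wp[["se.b2"]] <- w[["se.b2"]][perm]
  z1 <- channel_ggb(y[perm, , ], fg[perm, , ], wp)
  z2 <- channel_ggb(y, fg, w)[perm, , ]
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("shape mismatches are rejected", {
  w <- ggb_weights(10)
  expect_error(spatial_ggb(rand_feat(4, 3, 3, 1), rand_feat(4, 2, 3, 2), w),
               "differ")
  expect_error(channel_ggb(rand_feat(4, 3, 3, 1), rand_feat(4, 3, 2, 2), w),
               "differ")
})
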