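enc_cfg <- tiny_model_config()

test_that("pyramid stages come out at strides 4, 8, 16, 32", {
  w <- init_ugbnet(enc_cfg, seed = 1)
  img <- matrix(runif(64 * 64), 64, 64)
  pyr <- extract_pyramid(img, enc_cfg, w)
  sizes <- t(vapply(pyr, function(p) dim(p)[2:3], integer(2)))
  expect_equal(sizes, cbind(c(16, 8, 4, 2), c(16, 8, 4, 2)))
  expect_equal(vapply(pyr, attr, integer(1), "stride"), c(4L, 8L, 16L, 32L))
  expect_equal(vapply(pyr, function(p) dim(p)[1], integer(1)),
               enc_cfg$base_channels * c(1L, 2L, 4L, 8L))
  expect_error(extract_pyramid(matrix(0.5, 60, 64), enc_cfg, w), "divisible")
})

test_that("all-zero input with zero biases yields all-zero stage outputs", {
  w <- init_ugbnet(enc_cfg, seed = 2)   # conv biases are zero-initialized
  pyr <- extract_pyramid(matrix(0, 64, 64), enc_cfg, w)
  for (p in pyr) expect_equal(max(abs(p)), 0)
})

test_that("encoder path is deterministic for fixed weights and input", {
  w <- init_ugbnet(enc_cfg, seed = 3)
  img <- matrix(runif(64 * 64), 64, 64)
  p1 <- extract_pyramid(img, enc_cfg, w)
  p2 <- extract_pyramid(img, enc_cfg, w)
  expect_identical(p1, p2)
})

test_that("daspp preserves spatial size and enforces the rate bound", {
  cfg <- tiny_model_config(daspp_rates = c(1, 2, 3))
  w <- init_ugbnet(cfg, seed = 4)
  f <- array(rnorm(cfg$base_channels * 8 * 8 * 8), c(cfg$base_channels * 8, 8, 8))
  out <- daspp(f, cfg, w)
  expect_equal(dim(out)[2:3], c(8L, 8L))
  expect_equal(dim(out)[1], cfg$attention_channels)
  small <- array(rnorm(cfg$base_channels * 8 * 2 * 2), c(cfg$base_channels * 8, 2, 2))
  expect_error(daspp(small, cfg, w), "too large")
})

test_that("larger dilation rates enlarge the receptive field", {
  # gradient-support probe through the full daspp block
  support <- function(rates) {
    cfg <- tiny_model_config(daspp_rates = rates, base_channels = 1,
                             attention_channels = 4)
    w <- init_ugbnet(cfg, seed = 5)
    # positive weights + positive input keep every ReLU active, so the
    # gradient support equals the architectural receptive field
    for (nm in grep("^daspp", names(w), value = TRUE)) w[[nm]] <- abs(w[[nm]])
    set.seed(6)
    x <- ugbnet:::ag_tensor(array(runif(8 * 15 * 15, 0.1, 1), c(8, 15, 15, 1)), TRUE)
    out <- ugbnet:::nn_daspp(x, w, cfg)
    g <- array(0, dim(out$value)); g[1, 8, 8, 1] <- 1
    ugbnet:::ag_backward(out, g)
    sum(apply(x$grad[, , , 1, drop = FALSE], c(2, 3), function(v) any(v != 0)))
  }
  expect_gt(support(c(1, 3)), support(1))
  expect_gt(support(c(1, 3, 6)), support(c(1, 3)))
})

test_that("fusion resizes to stride 4, projects channels, and uses every stage", {
  w <- init_ugbnet(enc_cfg, seed = 6)
  img <- matrix(runif(64 * 64), 64, 64)
  pyr <- extract_pyramid(img, enc_cfg, w)
  f1 <- fuse_multiscale(pyr, enc_cfg, w)
  expect_equal(dim(f1)[1:3], c(enc_cfg$attention_channels, 16L, 16L))
  # ablation probe: zeroing any one stage changes F1
  for (s in 1:4) {
    ablated <- pyr
    ablated[[s]] <- ablated[[s]] * 0
    expect_gt(max(abs(fuse_multiscale(ablated, enc_cfg, w) - f1)), 1e-8)
  }
  expect_error(fuse_multiscale(pyr[1:3], enc_cfg, w), "4-stage")
})

test_that("fusing identical constant maps yields a spatially constant F1", {
  w <- init_ugbnet(enc_cfg, seed = 7)
  cs <- enc_cfg$base_channels * c(1L, 2L, 4L, 8L)
  hs <- c(16L, 8L, 4L, 2L)
  pyr <- purrr::map2(cs, hs, function(c, h) array(0.3, c(c, h, h)))
  f1 <- fuse_multiscale(pyr, enc_cfg, w)
  for (ch in seq_len(dim(f1)[1])) {
    expect_lt(diff(range(f1[ch, , , 1])), 1e-10)
  }
})

test_that("guidance map matches the target shape exactly", {
  w <- init_ugbnet(enc_cfg, seed = 8)
  ca <- enc_cfg$attention_channels
  f1 <- array(rnorm(ca * 16 * 16), c(ca, 16, 16))
  target <- array(0, c(ca, 4, 4))
  fg <- make_guidance(f1, target, w)
  expect_equal(dim(fg)[1:3], c(ca, 4L, 4L))
  # constant f1 stays constant through projection + resize
  fg2 <- make_guidance(array(1.5, c(ca, 16, 16)), target, w)
  for (ch in seq_len(ca)) expect_lt(diff(range(fg2[ch, , , 1])), 1e-10)
})

test_that("identity projection on a shape-matched f1 returns f1", {
  w <- init_ugbnet(enc_cfg, seed = 9)
  ca <- enc_cfg$attention_channels
  w[["guide.proj.W"]] <- array(0, c(ca, ca, 1, 1))
  for (k in seq_len(ca)) w[["guide.proj.W"]][k, k, 1, 1] <- 1
  w[["guide.proj.b"]][] <- 0
  f1 <- array(rnorm(ca * 4 * 4), c(ca, 4, 4))
  fg <- make_guidance(f1, f1, w)
  expect_equal(array(fg, dim(f1)), f1, tolerance = 1e-12)
})

test_that("reflective padding restores multiples of 32 and is cropped back", {
  img <- matrix(runif(50 * 70), 50, 70)
  p <- pad_to_multiple(img)
  expect_equal(dim(p$image) %% 32, c(0L, 0L))
  expect_equal(p$image[1:50, 1:70], img)
  expect_equal(p$orig, c(50L, 70L))
})
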