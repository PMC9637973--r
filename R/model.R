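# Architecture configuration, weight initialization, and the encoder-side
# stages: ResNet-style feature pyramid, dense atrous pyramid pooling (DASPP),
# multi-scale fusion, and the guidance-map projection.
#
# Weights live in a flat named list of arrays ("stem1.W", "enc.s2.b1.conv1.W",
# ...). Forward code and the initializer share the same stage-plan helper so
# the two cannot drift apart.

#' Network architecture configuration
#'
#' @param encoder_depth one of `"tiny"`, `18`, `50`, `101`. Depth 101 is the
#'   faithful default; `"tiny"` is a small basic-block variant sized for CPU
#'   tests. Depths 50/101 use bottleneck blocks, 18/"tiny" basic blocks.
#' @param base_channels channel width of the first encoder stage.
#' @param daspp_rates strictly increasing positive dilation rates of the
#'   densely connected atrous branches.
#' @param attention_channels channel count of the DASPP output, fusion map,
#'   guidance map and both attention blocks.
#' @param attention_stride stride (relative to the input image) at which the
#'   attention blocks operate; attention cost is quadratic in the number of
#'   positions, so 16 is the default and smaller values suit small images.
#' @param se_reduction bottleneck reduction ratio of the squeeze-and-excitation
#'   gate (clamped so the bottleneck has at least one unit).
#' @param head_threshold probability cutoff used by [predict_mask()].
#' @return a `model_config` object.
#' @export
model_config <- function(encoder_depth = 101, base_channels = 64,
                         daspp_rates = c(3, 6, 12, 18),
                         attention_channels = 64, attention_stride = 16,
                         se_reduction = 16, head_threshold = 0.5) {
  cfg <- list(
    encoder_depth = if (identical(encoder_depth, "tiny")) "tiny" else as.integer(encoder_depth),
    base_channels = as.integer(base_channels),
    daspp_rates = as.integer(daspp_rates),
    attention_channels = as.integer(attention_channels),
    attention_stride = as.integer(attention_stride),
    se_reduction = as.integer(se_reduction),
    head_threshold = head_threshold
  )
  if (!identical(cfg$encoder_depth, "tiny") &&
      !cfg$encoder_depth %in% c(18L, 50L, 101L)) {
    stop("encoder_depth must be 'tiny', 18, 50 or 101")
  }
  if (any(diff(cfg$daspp_rates) <= 0) || any(cfg$daspp_rates < 1)) {
    stop("daspp_rates must be strictly increasing positive integers")
  }
  if (cfg$attention_channels < 1) stop("attention_channels must be >= 1")
  if (!cfg$attention_stride %in% c(4L, 8L, 16L, 32L)) {
    stop("attention_stride must be one of 4, 8, 16, 32")
  }
  if (!(cfg$head_threshold > 0 && cfg$head_threshold < 1)) {
    stop("head_threshold must lie in (0, 1)")
  }
  cfg$se_reduction <- max(1L, min(cfg$se_reduction, cfg$attention_channels))
  class(cfg) <- "model_config"
  cfg
}

#' Small test-scale configuration
#'
#' Basic-block encoder with few channels, single-rate DASPP and attention at
#' stride 4 — sized so that training on 64x64 phantoms runs in CPU minutes.
#' At this image size the deepest stage is 2x2, which admits only dilation
#' rate 1, and stride-16 attention would see a 4x4 grid too coarse for thin
#' arc masks; stride 4 is the honest small-scale setting.
#' @param ... overrides passed on to [model_config()].
#' @export
tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(encoder_depth = "tiny", base_channels = 24, daspp_rates = 1L,
         attention_channels = 48, attention_stride = 4, se_reduction = 4),
    list(...))
  do.call(model_config, args)
}

# per-stage plan: blocks, block kind, mid/out channels, stride
encoder_plan <- function(config) {
  d <- config$encoder_depth
  c0 <- config$base_channels
  if (identical(d, "tiny") || identical(d, 18L)) {
    nb <- if (identical(d, "tiny")) c(1L, 1L, 1L, 1L) else c(2L, 2L, 2L, 2L)
    kind <- "basic"
    cout <- c0 * c(1L, 2L, 4L, 8L)
    cmid <- cout
  } else {
    nb <- if (identical(d, 50L)) c(3L, 4L, 6L, 3L) else c(3L, 4L, 23L, 3L)
    kind <- "bottleneck"
    cmid <- c0 * c(1L, 2L, 4L, 8L)
    cout <- 4L * cmid
  }
  list(nb = nb, kind = kind, cmid = cmid, cout = cout,
       stride = c(1L, 2L, 2L, 2L))
}

daspp_branch_channels <- function(config) {
  max(4L, config$attention_channels %/% 2L)
}

# ---- initialization ----

he_conv <- function(cout, cin, k, rng_sd = sqrt(2 / (cin * k * k))) {
  array(stats::rnorm(cout * cin * k * k, sd = rng_sd), c(cout, cin, k, k))
}

new_param_set <- function() new.env(parent = emptyenv())

add_conv <- function(W, name, cin, cout, k) {
  W[[paste0(name, ".W")]] <- he_conv(cout, cin, k)
  W[[paste0(name, ".b")]] <- numeric(cout)
  invisible(NULL)
}

#' Initialize network weights
#'
#' He (fan-in) initialization for every convolution; all biases zero. Returns
#' a flat named list of numeric arrays.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @param in_channels input image channels (1 for grayscale B-mode frames).
#' @export
init_ugbnet <- function(config, seed = 1L, in_channels = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  plan <- encoder_plan(config)
  c0 <- config$base_channels
  ca <- config$attention_channels
  W <- new.env(parent = emptyenv())
  add_conv(W, "stem1", in_channels, c0, 3L)
  add_conv(W, "stem2", c0, c0, 3L)
  cin <- c0
  for (s in 1:4) {
    for (b in seq_len(plan$nb[s])) {
      pre <- sprintf("enc.s%d.b%d", s, b)
      stride <- if (b == 1L) plan$stride[s] else 1L
      cout <- plan$cout[s]
      if (plan$kind == "basic") {
        add_conv(W, paste0(pre, ".conv1"), cin, cout, 3L)
        add_conv(W, paste0(pre, ".conv2"), cout, cout, 3L)
      } else {
        cm <- plan$cmid[s]
        add_conv(W, paste0(pre, ".conv1"), cin, cm, 1L)
        add_conv(W, paste0(pre, ".conv2"), cm, cm, 3L)
        add_conv(W, paste0(pre, ".conv3"), cm, cout, 1L)
      }
      if (cin != cout || stride != 1L) add_conv(W, paste0(pre, ".skip"), cin, cout, 1L)
      cin <- cout
    }
  }
  # DASPP: densely connected branches, then a 1x1 projection
  c5 <- plan$cout[4]
  cb <- daspp_branch_channels(config)
  acc <- c5
  for (i in seq_along(config$daspp_rates)) {
    add_conv(W, sprintf("daspp.br%d", i), acc, cb, 3L)
    acc <- acc + cb
  }
  add_conv(W, "daspp.proj", acc, ca, 1L)
  # multi-scale fusion of all four stages
  add_conv(W, "fuse.proj", sum(plan$cout), ca, 1L)
  # guidance projection
  add_conv(W, "guide.proj", ca, ca, 1L)
  # spatial attention: five independent 1x1 convs
  for (nm in c("alpha", "beta", "gamma", "eta", "rho")) {
    add_conv(W, paste0("ggb_s.", nm), ca, ca, 1L)
  }
  # squeeze-and-excitation gate of the channel block
  cr <- max(1L, ca %/% config$se_reduction)
  W[["se.P1"]] <- matrix(stats::rnorm(cr * ca, sd = sqrt(2 / ca)), cr, ca)
  # small positive bottleneck bias keeps the ReLU gate active at init
  W[["se.b1"]] <- rep(0.1, cr)
  W[["se.P2"]] <- matrix(stats::rnorm(ca * cr, sd = sqrt(2 / cr)), ca, cr)
  W[["se.b2"]] <- numeric(ca)
  # head reads the channel-refined map alongside the resized fusion map;
  # its bias starts at the logit of a sparse-foreground prior so the first
  # optimization steps are not spent collapsing to the background rate
  add_conv(W, "head", 2L * ca, 1L, 1L)
  W[["head.b"]] <- -2
  as.list(W)
}

# ---- node-level forward pieces (ag_node in, ag_node out) ----

wparam <- function(weights, name) {
  v <- weights[[name]]
  if (is.null(v)) stop("missing weight: ", name)
  if (inherits(v, "ag_node")) v else ag_tensor(v)
}

conv_block <- function(x, weights, name, stride = 1L, dilation = 1L, act = TRUE) {
  out <- ag_conv2d(x, wparam(weights, paste0(name, ".W")),
                   wparam(weights, paste0(name, ".b")),
                   stride = stride, dilation = dilation, pad = "same")
  if (act) ag_relu(out) else out
}

nn_pyramid <- function(x, weights, config) {
  plan <- encoder_plan(config)
  h <- conv_block(x, weights, "stem1", stride = 2L)
  h <- conv_block(h, weights, "stem2", stride = 2L)
  out <- vector("list", 4L)
  cin <- config$base_channels
  for (s in 1:4) {
    for (b in seq_len(plan$nb[s])) {
      pre <- sprintf("enc.s%d.b%d", s, b)
      stride <- if (b == 1L) plan$stride[s] else 1L
      cout <- plan$cout[s]
      skip <- if (cin != cout || stride != 1L) {
        conv_block(h, weights, paste0(pre, ".skip"), stride = stride, act = FALSE)
      } else h
      if (plan$kind == "basic") {
        m <- conv_block(h, weights, paste0(pre, ".conv1"), stride = stride)
        m <- conv_block(m, weights, paste0(pre, ".conv2"), act = FALSE)
      } else {
        m <- conv_block(h, weights, paste0(pre, ".conv1"))
        m <- conv_block(m, weights, paste0(pre, ".conv2"), stride = stride)
        m <- conv_block(m, weights, paste0(pre, ".conv3"), act = FALSE)
      }
      h <- ag_relu(ag_add(m, skip))
      cin <- cout
    }
    out[[s]] <- h
  }
  out
}

nn_daspp <- function(f, weights, config) {
  d <- dim(f$value)
  if (any(config$daspp_rates > min(d[2], d[3]))) {
    stop("daspp dilation rate ", max(config$daspp_rates),
         " too large for a ", d[2], "x", d[3], " feature map")
  }
  feats <- list(f)
  for (i in seq_along(config$daspp_rates)) {
    inp <- if (length(feats) == 1L) feats[[1]] else ag_concat_c(feats)
    br <- conv_block(inp, weights, sprintf("daspp.br%d", i),
                     dilation = config$daspp_rates[i])
    feats <- c(feats, list(br))
  }
  allf <- if (length(feats) == 1L) feats[[1]] else ag_concat_c(feats)
  conv_block(allf, weights, "daspp.proj")
}

nn_fuse <- function(pyramid, weights, config) {
  if (length(pyramid) != 4L) stop("expected a 4-stage pyramid, got ", length(pyramid))
  d2 <- dim(pyramid[[1]]$value)
  up <- lapply(pyramid, function(p) ag_resize_bilinear(p, d2[2], d2[3]))
  conv_block(ag_concat_c(up), weights, "fuse.proj")
}

nn_guidance <- function(f1, weights, target_h, target_w) {
  g <- conv_block(f1, weights, "guide.proj", act = FALSE)
  ag_resize_bilinear(g, target_h, target_w)
}

# ---- exported array-level operations ----

as_chwn <- function(x) {
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  if (length(dim(x)) == 3L) x <- array(x, c(dim(x), 1L))
  x
}

feature_map <- function(values, stride) structure(values, stride = stride)

#' Extract the four-stage encoder feature pyramid
#'
#' Runs the ResNet-style encoder and returns the four stage outputs at
#' strides 4, 8, 16 and 32 relative to the input (basic blocks: channels
#' `base_channels * c(1, 2, 4, 8)`; bottleneck: four times that).
#'
#' @param image h x w matrix in \[0, 1\] (or a (1, h, w, n) array batch);
#'   sides must be divisible by 32.
#' @param config a [model_config()].
#' @param weights from [init_ugbnet()].
#' @return list of four (c, h, w, n) arrays with a `stride` attribute.
#' @export
extract_pyramid <- function(image, config, weights) {
  x <- as_chwn(image)
  d <- dim(x)
  if (d[2] %% 32 != 0 || d[3] %% 32 != 0) {
    stop("image sides must be divisible by 32; use pad_to_multiple() first")
  }
  ag_no_grad({
    pyr <- nn_pyramid(ag_tensor(x), weights, config)
    vals <- lapply(pyr, function(p) p$value)
  })
  if (!all(vapply(vals, function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite encoder activations: corrupt weights or input")
  }
  purrr::map2(vals, c(4L, 8L, 16L, 32L), feature_map)
}

#' Dense atrous spatial pyramid pooling
#'
#' Densely connected parallel dilated 3x3 branches: branch i sees the input
#' concatenated with every earlier branch output; the input plus all branch
#' outputs are finally projected by a 1x1 convolution to
#' `attention_channels`. Spatial size is preserved.
#'
#' @param feature (c, h, w) or (c, h, w, n) array — the deepest stage output.
#' @inheritParams extract_pyramid
#' @return (attention_channels, h, w, n) array.
#' @export
daspp <- function(feature, config, weights) {
  x <- as_chwn(feature)
  ag_no_grad(out <- nn_daspp(ag_tensor(x), weights, config)$value)
  feature_map(out, attr(feature, "stride") %||% 32L)
}

#' Multi-scale fusion map
#'
#' Bilinearly resizes every pyramid stage to the stride-4 resolution,
#' concatenates along channels and projects with a 1x1 convolution into the
#' fusion map `F1` (`attention_channels` channels), which combines shallow
#' detail with deep semantics and serves as the guidance source.
#'
#' @param pyramid list of four stage arrays from [extract_pyramid()].
#' @inheritParams extract_pyramid
#' @export
fuse_multiscale <- function(pyramid, config, weights) {
  nodes <- lapply(pyramid, function(p) ag_tensor(as_chwn(p)))
  ag_no_grad(out <- nn_fuse(nodes, weights, config)$value)
  feature_map(out, 4L)
}

#' Project and resize the fusion map into a guidance map
#'
#' 1x1 convolution of `F1` followed by bilinear resizing so the guidance map
#' `FG` exactly matches the channel count and spatial size of `target`.
#'
#' @param f1 fusion map array.
#' @param target feature array whose shape `FG` must match (e.g. the DASPP
#'   output).
#' @param weights from [init_ugbnet()].
#' @export
make_guidance <- function(f1, target, weights) {
  x <- as_chwn(f1)
  td <- dim(as_chwn(target))
  ag_no_grad(out <- nn_guidance(ag_tensor(x), weights, td[2], td[3])$value)
  feature_map(out, attr(target, "stride") %||% NULL)
}

#' Reflectively pad an image to side multiples of 32
#'
#' @param image h x w matrix.
#' @return list with `image` (padded) and `orig` (original h, w).
#' @export
pad_to_multiple <- function(image, multiple = 32L) {
  d <- dim(image)
  ph <- (multiple - d[1] %% multiple) %% multiple
  pw <- (multiple - d[2] %% multiple) %% multiple
  if (ph > 0) image <- rbind(image, image[d[1] - seq_len(ph) + 1, , drop = FALSE])
  if (pw > 0) image <- cbind(image, image[, d[2] - seq_len(pw) + 1, drop = FALSE])
  list(image = image, orig = d)
}
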