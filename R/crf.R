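# Fully connected CRF refinement of the network's probability map by
# mean-field inference: two-label model with unary potentials from the
# (clamped) network probabilities and Gaussian + bilateral pairwise
# potentials under a Potts compatibility. Self-contained: an exact dense
# pairwise kernel is used for small images, a truncated-window pass for
# large ones.

#' Dense-CRF parameters
#'
#' Kernel defaults follow the dense-CRF literature for natural-image
#' segmentation. Intensity differences for the bilateral kernel are measured
#' in 8-bit gray levels (image values in \[0, 1\] are scaled by 255).
#'
#' @param iterations mean-field iterations.
#' @param spatial_sigma bandwidth (pixels) of the smoothness-only Gaussian
#'   kernel.
#' @param bilateral_sigma_xy spatial bandwidth (pixels) of the bilateral
#'   (appearance) kernel.
#' @param bilateral_sigma_intensity intensity bandwidth (gray levels) of the
#'   bilateral kernel.
#' @param spatial_weight,bilateral_weight nonnegative kernel weights; zero
#'   weights reduce refinement to the identity.
#' @export
crf_params <- function(iterations = 5L, spatial_sigma = 3,
                       bilateral_sigma_xy = 30, bilateral_sigma_intensity = 13,
                       spatial_weight = 3, bilateral_weight = 5) {
  p <- list(iterations = as.integer(iterations), spatial_sigma = spatial_sigma,
            bilateral_sigma_xy = bilateral_sigma_xy,
            bilateral_sigma_intensity = bilateral_sigma_intensity,
            spatial_weight = spatial_weight, bilateral_weight = bilateral_weight)
  if (p$iterations < 1) stop("iterations must be >= 1")
  if (p$spatial_sigma <= 0 || p$bilateral_sigma_xy <= 0 ||
      p$bilateral_sigma_intensity <= 0) stop("all sigmas must be positive")
  if (p$spatial_weight < 0 || p$bilateral_weight < 0) {
    stop("kernel weights must be nonnegative")
  }
  class(p) <- "crf_params"
  p
}

# exact pairwise operator for small images: K q, with K the weighted sum of
# the spatial and bilateral Gaussian kernels, zero diagonal
crf_dense_operator <- function(image, params) {
  h <- nrow(image); w <- ncol(image)
  ys <- rep(seq_len(h), times = w)
  xs <- rep(seq_len(w), each = h)
  iv <- as.vector(image) * 255
  d2 <- outer(ys, ys, "-")^2 + outer(xs, xs, "-")^2
  K <- params$spatial_weight * exp(-d2 / (2 * params$spatial_sigma^2))
  K <- K + params$bilateral_weight *
    exp(-d2 / (2 * params$bilateral_sigma_xy^2)) *
    exp(-outer(iv, iv, "-")^2 / (2 * params$bilateral_sigma_intensity^2))
  diag(K) <- 0
  function(q) K %*% q
}

# truncated-window pairwise operator for large images: offsets within a
# radius cap (documented approximation of the fully connected kernels)
crf_window_operator <- function(image, params, radius_cap = 12L) {
  h <- nrow(image); w <- ncol(image)
  iv <- image * 255
  rs <- min(ceiling(3 * params$spatial_sigma), radius_cap)
  rb <- min(ceiling(3 * params$bilateral_sigma_xy), radius_cap)
  r <- max(rs, rb)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  offs$d2 <- offs$di^2 + offs$dj^2
  offs <- offs[offs$d2 <= r^2, ]
  function(q) {
    qm <- matrix(q, h, w)
    out <- matrix(0, h, w)
    for (k in seq_len(nrow(offs))) {
      di <- offs$di[k]; dj <- offs$dj[k]; d2 <- offs$d2[k]
      if (max(1, 1 - di) > min(h, h - di) ||
          max(1, 1 - dj) > min(w, w - dj)) next
      ri <- max(1, 1 - di):min(h, h - di)
      ci <- max(1, 1 - dj):min(w, w - dj)
      src_r <- ri + di; src_c <- ci + dj
      contrib <- 0
      if (d2 <= rs^2) {
        contrib <- contrib + params$spatial_weight *
          exp(-d2 / (2 * params$spatial_sigma^2)) * qm[src_r, src_c]
      }
      if (d2 <= rb^2) {
        contrib <- contrib + params$bilateral_weight *
          exp(-d2 / (2 * params$bilateral_sigma_xy^2)) *
          exp(-(iv[ri, ci] - iv[src_r, src_c])^2 /
                (2 * params$bilateral_sigma_intensity^2)) * qm[src_r, src_c]
      }
      out[ri, ci] <- out[ri, ci] + contrib
    }
    as.vector(out)
  }
}

#' Refine a probability map with a fully connected CRF
#'
#' Mean-field inference on a two-label dense CRF. Unary potentials are the
#' negative log of the clamped network probabilities; pairwise potentials
#' are a spatial Gaussian kernel plus a bilateral (position x intensity)
#' kernel under Potts compatibility. Marginals are re-normalized at every
#' iteration by construction; with both pairwise weights zero the output
#' equals the input. Images up to `dense_max_pixels` use the exact dense
#' kernel; larger images a truncated-window approximation.
#'
#' @param image the grayscale frame (`image_sample` or h x w matrix in
#'   \[0, 1\]) whose intensities drive the bilateral kernel.
#' @param prob h x w foreground probability map.
#' @param params a [crf_params()].
#' @param dense_max_pixels pixel-count limit of the exact dense path.
#' @param trace if TRUE, attach the per-iteration foreground and background
#'   marginals as attribute `"trace"`.
#' @return refined h x w foreground probability map in \[0, 1\].
#' @export
refine_crf <- function(image, prob, params = crf_params(),
                       dense_max_pixels = 6400L, trace = FALSE) {
  img <- if (inherits(image, "image_sample")) image$image else image
  stopifnot(identical(dim(img), dim(prob)))
  h <- nrow(img); w <- ncol(img)
  eps <- 1e-6
  p <- pmin(pmax(prob, eps), 1 - eps)
  u_fg <- -log(as.vector(p))
  u_bg <- -log(as.vector(1 - p))
  if (params$spatial_weight == 0 && params$bilateral_weight == 0) {
    kop <- function(q) 0 * q
  } else if (h * w <= dense_max_pixels) {
    kop <- crf_dense_operator(img, params)
  } else {
    kop <- crf_window_operator(img, params)
  }
  q_fg <- as.vector(p)
  q_bg <- 1 - q_fg
  tr <- if (trace) vector("list", params$iterations) else NULL
  for (it in seq_len(params$iterations)) {
    e_fg <- u_fg + kop(q_bg)       # Potts: cost from the opposite label
    e_bg <- u_bg + kop(q_fg)
    m <- pmin(e_fg, e_bg)
    a <- exp(-(e_fg - m)); b <- exp(-(e_bg - m))
    q_fg <- as.vector(a / (a + b))
    q_bg <- as.vector(b / (a + b))
    if (trace) tr[[it]] <- list(fg = matrix(q_fg, h, w), bg = matrix(q_bg, h, w))
  }
  out <- matrix(q_fg, h, w)
  if (trace) attr(out, "trace") <- tr
  out
}
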