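#' Parameters of the synthetic spinal-ultrasound phantom
#'
#' The phantom emulates the appearance of paraspinal B-mode frames: bright
#' downward-opening arc echoes where the beam meets bone (spinous/transverse
#' processes, laminae), granular multiplicative speckle over soft tissue, and
#' dark acoustic-shadow columns beneath each bone surface where little
#' acoustic energy penetrates. It makes no attempt at wave-propagation
#' physics; it supplies paired images and ground-truth masks with the gross
#' statistics a bone-segmentation network must latch onto.
#'
#' @param height,width frame size in pixels. The default matches the 640x480
#'   grayscale frames typical of freehand 2-D ultrasound acquisition; tests
#'   use 64x64.
#' @param n_arcs number of bone-echo arcs per frame.
#' @param arc_intensity echo brightness of bone pixels, in \[0, 1\]; must
#'   exceed `background_level`.
#' @param arc_thickness radial thickness of the rendered arc, pixels.
#' @param speckle_shape shape parameter of the unit-mean gamma multiplicative
#'   speckle; smaller values give grainier images.
#' @param shadow_attenuation multiplicative factor in \[0, 1\] applied to every
#'   pixel lying below an arc in the same column.
#' @param background_level mean soft-tissue brightness in \[0, 1\].
#' @param mask_area_bounds length-2 numeric `(min_frac, max_frac)`: admissible
#'   foreground fraction of the mask; arc placement is re-drawn until the
#'   fraction falls inside these bounds.
#' @param seed integer seed; together with the sample index it fully
#'   determines each generated frame.
#' @return an object of class `phantom_params` (a validated list).
#' @export
phantom_params <- function(height = 480L, width = 640L, n_arcs = 3L,
                           arc_intensity = 0.9, arc_thickness = 5L,
                           speckle_shape = 4, shadow_attenuation = 0.35,
                           background_level = 0.25,
                           mask_area_bounds = c(0.01, 0.2), seed = 1L) {
  p <- list(
    height = as.integer(height), width = as.integer(width),
    n_arcs = as.integer(n_arcs), arc_intensity = arc_intensity,
    arc_thickness = as.integer(arc_thickness), speckle_shape = speckle_shape,
    shadow_attenuation = shadow_attenuation,
    background_level = background_level,
    mask_area_bounds = as.numeric(mask_area_bounds), seed = as.integer(seed)
  )
  if (p$height < 8 || p$width < 8) stop("phantom frames must be at least 8x8")
  if (p$n_arcs < 0) stop("n_arcs must be nonnegative")
  if (!(p$background_level >= 0 && p$background_level < p$arc_intensity &&
        p$arc_intensity <= 1)) {
    stop("need 0 <= background_level < arc_intensity <= 1")
  }
  if (!(p$speckle_shape > 0)) stop("speckle_shape must be positive")
  if (!(p$shadow_attenuation >= 0 && p$shadow_attenuation <= 1)) {
    stop("shadow_attenuation must lie in [0, 1]")
  }
  b <- p$mask_area_bounds
  if (!(length(b) == 2 && b[1] > 0 && b[1] < b[2] && b[2] < 0.5)) {
    stop("mask_area_bounds must satisfy 0 < min_frac < max_frac < 0.5")
  }
  class(p) <- "phantom_params"
  p
}

# deterministic 31-bit stream seed for (seed, index)
phantom_stream_seed <- function(seed, index) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + (as.double(index) + 1) * 69621) %% 2147483647
  as.integer(x)
}

# render n_arcs downward-opening circular arc segments; returns binary h x w mask
render_arcs <- function(p) {
  h <- p$height; w <- p$width
  yy <- matrix(seq_len(h), h, w)          # depth (row)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- matrix(0, h, w)
  for (a in seq_len(p$n_arcs)) {
    r <- stats::runif(1, 0.12, 0.3) * w
    cx <- stats::runif(1, 0.15 * w, 0.85 * w)
    # circle centre sits below the arc: the visible cap is its top
    apex <- stats::runif(1, 0.2 * h, 0.7 * h)
    cy <- apex + r
    span <- stats::runif(1, 0.25, 0.55)    # half-angle from vertical, radians
    dist <- sqrt((xx - cx)^2 + (yy - cy)^2)
    ang <- atan2(cx - xx, cy - yy)         # 0 = straight up from centre
    hit <- abs(dist - r) <= p$arc_thickness / 2 & yy <= cy & abs(ang) <= span
    mask[hit] <- 1
  }
  mask
}

#' Generate one synthetic ultrasound frame with its bone mask
#'
#' Deterministic in `(params$seed, index)`: the same pair always yields a
#' bit-identical image and mask. Arc placement is re-drawn (bounded retries)
#' until the foreground fraction falls inside `params$mask_area_bounds`.
#'
#' @param params a [phantom_params()] object.
#' @param index nonnegative sample index within the stream.
#' @return an `image_sample`: list with `image` (h x w matrix in \[0, 1\]),
#'   `mask` (h x w binary matrix) and `id`.
#' @examples
#' s <- generate_phantom(phantom_params(height = 64, width = 64), 0)
#' mean(s$image[s$mask == 1]) > mean(s$image[s$mask == 0])
#' @export
generate_phantom <- function(params, index = 0L) {
  stopifnot(inherits(params, "phantom_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(phantom_stream_seed(params$seed, index))
  h <- params$height; w <- params$width
  mask <- NULL
  if (params$n_arcs == 0) {
    mask <- matrix(0, h, w)
  } else {
    for (try in seq_len(50L)) {
      cand <- render_arcs(params)
      f <- mean(cand)
      if (f >= params$mask_area_bounds[1] && f <= params$mask_area_bounds[2]) {
        mask <- cand
        break
      }
    }
    if (is.null(mask)) {
      stop("could not place arcs with foreground fraction in mask_area_bounds ",
           "after 50 attempts; parameters are inconsistent")
    }
  }
  scene <- matrix(params$background_level, h, w)
  scene[mask == 1] <- params$arc_intensity
  # acoustic shadow: attenuate everything below an arc in the same column
  for (j in seq_len(w)) {
    rows <- which(mask[, j] == 1)
    if (length(rows) && max(rows) < h) {
      scene[(max(rows) + 1):h, j] <- scene[(max(rows) + 1):h, j] * params$shadow_attenuation
    }
  }
  speckle <- matrix(
    stats::rgamma(h * w, shape = params$speckle_shape,
                  scale = 1 / params$speckle_shape), h, w)
  img <- pmin(pmax(scene * speckle, 0), 1)
  image_sample(img, mask, id = sprintf("phantom_%04d", index))
}

#' Construct an image sample
#'
#' @param image h x w numeric matrix with values in \[0, 1\].
#' @param mask optional h x w binary matrix of the same size.
#' @param id character identifier.
#' @return an `image_sample` list.
#' @export
image_sample <- function(image, mask = NULL, id = "sample") {
  stopifnot(is.matrix(image), all(is.finite(image)),
            min(image) >= 0, max(image) <= 1)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(image)), all(mask %in% c(0, 1)))
  }
  structure(list(image = image, mask = mask, id = id), class = "image_sample")
}

#' Generate a phantom dataset
#'
#' Samples are independent given distinct indices: each index has its own
#' random stream derived from `(params$seed, index)`, so generation order
#' (and parallel generation) cannot change any sample.
#'
#' @param params a [phantom_params()] object.
#' @param n number of samples (ids `phantom_0000` ...).
#' @return list of `image_sample` objects.
#' @export
generate_dataset <- function(params, n) {
  stopifnot(n >= 1)
  lapply(seq_len(n) - 1L, function(i) generate_phantom(params, i))
}
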