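# PNG dataset layout: `{id}.png` grayscale frames in [0, 255], optional
# `{id}_mask.png` binary masks in {0, 255}.

to_gray <- function(px) {
  if (length(dim(px)) == 3L) px <- apply(px[, , seq_len(min(3, dim(px)[3])), drop = FALSE],
                                         c(1, 2), mean)
  px
}

# 8-bit quantization: round(x * 255), R's round-half-to-even at exact .5
# boundaries (so 0.5 stores as gray value 128)
quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255)

read_png_checked <- function(path) {
  tryCatch(png::readPNG(path),
           error = function(e) stop("unreadable PNG: ", path, " (", conditionMessage(e), ")"))
}

#' Load an image/mask dataset from a directory
#'
#' Expects the `{id}.png` / `{id}_mask.png` layout. Images are scaled to
#' \[0, 1\]; masks are binarized at gray value 128 of 255. A missing mask is
#' allowed (inference mode); an unreadable file is a hard error naming the
#' path. Samples are returned sorted by id.
#'
#' @param root dataset directory.
#' @return list of `image_sample` objects.
#' @export
load_dataset <- function(root) {
  files <- list.files(root, pattern = "\\.png$")
  ids <- sort(sub("\\.png$", "", files[!grepl("_mask\\.png$", files)]))
  lapply(ids, function(id) {
    img <- to_gray(read_png_checked(file.path(root, paste0(id, ".png"))))
    mask_path <- file.path(root, paste0(id, "_mask.png"))
    mask <- NULL
    if (file.exists(mask_path)) {
      mask <- (to_gray(read_png_checked(mask_path)) >= 128 / 255) * 1
    }
    image_sample(img, mask, id = id)
  })
}

#' Write samples as PNG image/mask pairs
#'
#' @param samples list of `image_sample` objects.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_dataset <- function(samples, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- unlist(lapply(samples, function(s) {
    ip <- file.path(out_dir, paste0(s$id, ".png"))
    png::writePNG(quantize8(s$image) / 255, ip)
    out <- ip
    if (!is.null(s$mask)) {
      mp <- file.path(out_dir, paste0(s$id, "_mask.png"))
      png::writePNG(s$mask, mp)
      out <- c(out, mp)
    }
    out
  }))
  invisible(paths)
}

#' Save a prediction as probability and mask PNGs
#'
#' Writes `{id}_prob.png` (probabilities linearly mapped to \[0, 255\],
#' round-half-to-even) and `{id}_mask.png` (values {0, 255}).
#'
#' @param prob h x w probability matrix.
#' @param mask h x w binary matrix.
#' @param out_dir output directory.
#' @param id sample identifier.
#' @return character vector of the two written paths.
#' @export
save_prediction <- function(prob, mask, out_dir, id) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(out_dir, paste0(id, "_prob.png"))
  mp <- file.path(out_dir, paste0(id, "_mask.png"))
  png::writePNG(quantize8(prob) / 255, pp)
  png::writePNG(mask, mp)
  c(prob = pp, mask = mp)
}

#' Read / write a flat YAML configuration
#'
#' Keys prefixed `model_`, `train_`, `phantom_` and `crf_` map onto the
#' corresponding constructor arguments; [resolve_configs()] splits a flat
#' list into the four constructor calls.
#'
#' @param path YAML file path.
#' @export
load_config <- function(path) yaml::read_yaml(path)

#' @rdname load_config
#' @param cfg flat named list.
#' @param out optional path; the resolved configuration is dumped there as
#'   YAML (runs record their own settings).
#' @export
resolve_configs <- function(cfg, out = NULL) {
  pick <- function(prefix, ctor) {
    keys <- grep(paste0("^", prefix, "_"), names(cfg), value = TRUE)
    args <- stats::setNames(cfg[keys], sub(paste0("^", prefix, "_"), "", keys))
    if (prefix == "model" && identical(args$encoder_depth, "tiny")) {
      # the tiny depth carries its own scaled-down defaults
      args$encoder_depth <- NULL
      ctor <- tiny_model_config
    }
    do.call(ctor, args)
  }
  res <- list(model = pick("model", model_config),
              train = pick("train", train_config),
              phantom = pick("phantom", phantom_params),
              crf = pick("crf", crf_params))
  if (!is.null(out)) {
    yaml::write_yaml(lapply(res, unclass), out)
  }
  res
}
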