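# Full forward pass: encoder -> DASPP -> fusion -> guidance -> spatial GGB
# -> channel GGB -> 1x1 head -> bilinear upsample -> sigmoid.

# node-level forward on a padded (1, h, w, n) batch; returns logits at full
# resolution plus intermediates when requested
nn_forward <- function(x, weights, config, collect = FALSE) {
  d <- dim(x$value)
  pyr <- nn_pyramid(x, weights, config)
  fx <- nn_daspp(pyr[[4]], weights, config)
  f1 <- nn_fuse(pyr, weights, config)
  ah <- d[2] %/% config$attention_stride
  aw <- d[3] %/% config$attention_stride
  fx_att <- ag_resize_bilinear(fx, ah, aw)
  fg <- nn_guidance(f1, weights, ah, aw)
  sp <- nn_spatial_ggb(fx_att, fg, weights, collect = collect)
  ch <- nn_channel_ggb(sp$y, fg, weights, collect = collect)
  # prediction head: 1x1 convolution over the channel-refined map fused with
  # the multi-scale map, so fine stride-4 detail reaches the output directly
  f1_att <- ag_resize_bilinear(f1, ah, aw)
  logits <- conv_block(ag_concat_c(list(ch$z, f1_att)), weights, "head", act = FALSE)
  logits <- ag_resize_bilinear(logits, d[2], d[3])
  out <- list(logits = logits)
  if (collect) {
    out$stages <- list(pyramid = pyr, fx = fx, f1 = f1, fg = fg,
                       y = sp$y, z = ch$z)
    out$sims <- c(sp$sims, ch$sims)
  }
  out
}

#' Forward pass of the segmentation network
#'
#' Runs the full pipeline on one grayscale frame and returns the foreground
#' probability map at input resolution. Images whose sides are not multiples
#' of 32 are reflectively padded and the output cropped back. Deterministic
#' for fixed weights and input.
#'
#' @param sample an `image_sample` (or a plain h x w matrix in \[0, 1\]).
#' @param config a [model_config()].
#' @param weights from [init_ugbnet()] or [train_ugbnet()].
#' @param collect_sims also return every similarity matrix of the forward
#'   pass (row-stochastic (hw, hw) and (c, c) arrays).
#' @return h x w matrix of probabilities in \[0, 1\]; with
#'   `collect_sims = TRUE` a list with `prob` and `sims`.
#' @export
ugbnet_forward <- function(sample, config, weights, collect_sims = FALSE) {
  img <- if (inherits(sample, "image_sample")) sample$image else sample
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= 1)
  padded <- pad_to_multiple(img)
  x <- array(padded$image, c(1L, dim(padded$image), 1L))
  ag_no_grad(res <- nn_forward(ag_tensor(x), weights, config,
                               collect = collect_sims))
  lg <- res$logits$value
  if (!all(is.finite(lg))) stop("non-finite network output at the head stage")
  prob <- 1 / (1 + exp(-lg[1, , , 1]))
  prob <- prob[seq_len(padded$orig[1]), seq_len(padded$orig[2]), drop = FALSE]
  if (collect_sims) list(prob = prob, sims = res$sims) else prob
}

#' Threshold a probability map into a binary mask
#'
#' @param prob numeric array of probabilities.
#' @param threshold cutoff in (0, 1); pixels with `prob >= threshold` are
#'   foreground (ties count as foreground).
#' @export
predict_mask <- function(prob, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (prob >= threshold) * 1
}

#' Save / load a model checkpoint
#'
#' Weights go to an `.rds` file; the architecture configuration goes to a
#' JSON sidecar (`<path>.json`) so a checkpoint is self-describing.
#'
#' @param weights flat named list of weight arrays.
#' @param config the [model_config()] the weights belong to.
#' @param path checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(weights, config, path) {
  saveRDS(weights, path)
  jsonlite::write_json(unclass(config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()`: list with `weights` and `config`.
#' @export
load_checkpoint <- function(path) {
  weights <- readRDS(path)
  cj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cj$daspp_rates <- as.integer(cj$daspp_rates)
  list(weights = weights, config = do.call(model_config, cj))
}
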