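# Adam optimization of the binary cross-entropy objective, plus the k-fold
# cross-validation harness over pluggable models.

#' Optimization configuration
#'
#' Defaults follow the protocol the network was designed around: Adam with
#' learning rate 0.001 and moments (0.9, 0.999), 50 epochs, batch size 8,
#' four cross-validation folds.
#'
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param folds number of cross-validation folds.
#' @param seed integer seed controlling initialization, shuffling and fold
#'   assignment.
#' @param holdout_frac fraction of the training set held out for the
#'   per-epoch Dice curve (0 disables the split; the curve then tracks the
#'   training set itself).
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param max_steps optional hard cap on optimization steps (default
#'   unlimited); useful for fixed-budget capacity checks.
#' @param eval_every evaluate the monitored Dice every this many epochs
#'   (`NA` in the history rows in between).
#' @param device compute-target label (informational; only "cpu" exists).
#' @export
train_config <- function(learning_rate = 0.001, epochs = 50L, batch_size = 8L,
                         folds = 4L, seed = 1L, holdout_frac = 0.1,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         max_steps = Inf, eval_every = 1L, device = "cpu") {
  cfg <- list(learning_rate = learning_rate, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), folds = as.integer(folds),
              seed = as.integer(seed), holdout_frac = holdout_frac,
              beta1 = beta1, beta2 = beta2, eps = eps,
              max_steps = max_steps, eval_every = as.integer(eval_every),
              device = device)
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$epochs < 0 || cfg$batch_size < 1 || cfg$folds < 1) {
    stop("epochs, batch_size and folds must be positive counts")
  }
  class(cfg) <- "train_config"
  cfg
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) array(0, dim(w) %||% length(w))),
       v = lapply(weights, function(w) array(0, dim(w) %||% length(w))),
       t = 0L)
}

adam_step <- function(weights, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    weights[[nm]] <- weights[[nm]] - cfg$learning_rate *
      (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + cfg$eps)
  }
  list(weights = weights, state = state)
}

stack_batch <- function(samples) {
  d <- dim(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(1L, d[1], d[2], n))
  y <- array(0, c(1L, d[1], d[2], n))
  for (i in seq_len(n)) {
    x[1, , , i] <- samples[[i]]$image
    y[1, , , i] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

batch_dice <- function(samples, config, weights) {
  vals <- vapply(samples, function(s) {
    prob <- ugbnet_forward(s, config, weights)
    dice(predict_mask(prob, config$head_threshold), s$mask)
  }, numeric(1))
  mean(vals)
}

#' Train the network on labelled samples
#'
#' Shuffled mini-batch Adam on the mean binary cross-entropy between the
#' network's probability map and the ground-truth mask. Fully seeded:
#' initialization, shuffling and the holdout split all derive from
#' `train_config$seed`, so identical calls give identical histories.
#'
#' @param dataset list of `image_sample` objects, all with masks, with sides
#'   divisible by 32.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @param weights optional warm-start weights (default: fresh
#'   [init_ugbnet()]).
#' @return an object of class `ugb_fit`: list with `weights`, `config`,
#'   `train_config` and `history` (tibble with `epoch`, `loss`, `dice`).
#' @export
train_ugbnet <- function(dataset, model_cfg, train_cfg, weights = NULL) {
  if (!all(vapply(dataset, function(s) !is.null(s$mask), logical(1)))) {
    stop("every training sample needs a mask")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (is.null(weights)) weights <- init_ugbnet(model_cfg, seed = train_cfg$seed)
  set.seed(train_cfg$seed + 1L)
  n <- length(dataset)
  n_hold <- floor(train_cfg$holdout_frac * n)
  hold_idx <- if (n_hold > 0) sample.int(n, n_hold) else integer(0)
  train_idx <- setdiff(seq_len(n), hold_idx)
  eval_set <- if (n_hold > 0) dataset[hold_idx] else dataset
  state <- adam_init(weights)
  history <- vector("list", train_cfg$epochs)
  step <- 0L
  for (ep in seq_len(train_cfg$epochs)) {
    perm <- sample(train_idx)
    losses <- c()
    for (b0 in seq(1, length(perm), by = train_cfg$batch_size)) {
      idx <- perm[b0:min(b0 + train_cfg$batch_size - 1L, length(perm))]
      bt <- stack_batch(dataset[idx])
      nodes <- lapply(weights, ag_tensor, requires_grad = TRUE)
      out <- nn_forward(ag_tensor(bt$x), nodes, model_cfg)
      loss <- ag_bce_logits(out$logits, bt$y)
      if (!is.finite(loss$value)) {
        stop(sprintf("NaN/Inf loss at epoch %d, batch starting %d", ep, b0))
      }
      ag_backward(loss)
      upd <- adam_step(weights, lapply(nodes, function(nd) nd$grad),
                       state, train_cfg)
      weights <- upd$weights
      state <- upd$state
      losses <- c(losses, loss$value)
      step <- step + 1L
      if (step >= train_cfg$max_steps) break
    }
    last <- step >= train_cfg$max_steps || ep == train_cfg$epochs
    history[[ep]] <- tibble::tibble(
      epoch = ep, loss = mean(losses),
      dice = if (last || ep %% train_cfg$eval_every == 0L) {
        batch_dice(eval_set, model_cfg, weights)
      } else NA_real_)
    if (step >= train_cfg$max_steps) break
  }
  structure(list(weights = weights, config = model_cfg,
                 train_config = train_cfg,
                 history = dplyr::bind_rows(history)),
            class = "ugb_fit")
}

#' Predict probability maps for new samples
#'
#' @param object a fitted `ugb_fit`.
#' @param samples list of `image_sample` objects (or one sample).
#' @param type `"prob"` for probability maps, `"mask"` for thresholded
#'   binary masks.
#' @param ... unused.
#' @return tibble with columns `id`, `prob` (list of matrices) and, for
#'   `type = "mask"`, `mask`.
#' @export
predict.ugb_fit <- function(object, samples, type = c("prob", "mask"), ...) {
  type <- match.arg(type)
  if (inherits(samples, "image_sample")) samples <- list(samples)
  probs <- lapply(samples, function(s) ugbnet_forward(s, object$config, object$weights))
  out <- tibble::tibble(
    id = vapply(samples, function(s) s$id, character(1)),
    prob = probs)
  if (type == "mask") {
    out$mask <- lapply(probs, predict_mask, threshold = object$config$head_threshold)
  }
  out
}

#' Assign samples to cross-validation folds
#'
#' Seeded shuffle followed by contiguous chunking into `folds` disjoint,
#' covering, near-equal test folds.
#'
#' @param n number of samples.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold labels (1..folds) per sample.
#' @export
fold_assignment <- function(n, folds, seed = 1L) {
  if (n < folds) stop("need at least as many samples as folds")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lab <- integer(n)
  at <- 0L
  for (f in seq_len(folds)) {
    lab[perm[(at + 1):(at + sizes[f])]] <- f
    at <- at + sizes[f]
  }
  lab
}

#' Model factory for the full network
#'
#' A model factory is `function(train_samples, model_cfg, train_cfg)`
#' returning a predictor `function(sample) -> probability matrix`. This one
#' trains the network; [oracle_model_factory()] returns the ground truth
#' (a perfect-predictor control) and [constant_model_factory()] a constant
#' map — both useful for validating the harness itself.
#' @export
ugbnet_model_factory <- function(train_samples, model_cfg, train_cfg) {
  fit <- train_ugbnet(train_samples, model_cfg, train_cfg)
  function(sample) ugbnet_forward(sample, fit$config, fit$weights)
}

#' @rdname ugbnet_model_factory
#' @export
oracle_model_factory <- function(train_samples, model_cfg, train_cfg) {
  function(sample) sample$mask + 0
}

#' @rdname ugbnet_model_factory
#' @param level constant probability the factory-made model outputs.
#' @export
constant_model_factory <- function(level = 0) {
  function(train_samples, model_cfg, train_cfg) {
    function(sample) matrix(level, nrow(sample$image), ncol(sample$image))
  }
}

#' k-fold cross-validation of a segmentation model
#'
#' Partitions the dataset into `train_cfg$folds` disjoint test folds
#' (seeded shuffle, contiguous chunks), trains the factory's model on each
#' complement, and scores Dice/Jaccard/precision/recall per test image.
#' Metrics are computed per image and averaged within a fold; the aggregate
#' is the mean and population standard deviation across folds, conventionally
#' reported in percent as `mean +/- sd`.
#'
#' @param dataset list of `image_sample` objects with masks.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()] (supplies `folds` and `seed`).
#' @param model_factory see [ugbnet_model_factory()] (the default).
#' @return an object of class `ugb_cv`: list with `per_image`, `per_fold`
#'   and `aggregate` tibbles and the fold labels.
#' @export
cross_validate <- function(dataset, model_cfg, train_cfg,
                           model_factory = ugbnet_model_factory) {
  folds <- train_cfg$folds
  lab <- fold_assignment(length(dataset), folds, train_cfg$seed)
  per_image <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(lab == f)
    if (!length(test_idx)) stop("fold ", f, " has no test samples")
    predictor <- model_factory(dataset[-test_idx], model_cfg, train_cfg)
    rows <- lapply(test_idx, function(i) {
      s <- dataset[[i]]
      prob <- predictor(s)
      m <- seg_metrics(predict_mask(prob, model_cfg$head_threshold), s$mask)
      dplyr::bind_cols(tibble::tibble(fold = f, id = s$id), m)
    })
    per_image[[f]] <- dplyr::bind_rows(rows)
  }
  per_image <- dplyr::bind_rows(per_image)
  per_fold <- per_image |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(dplyr::across(c("dice", "jaccard", "precision", "recall"),
                                   mean), .groups = "drop")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  aggregate <- per_fold |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = pop_sd(.data$value),
                     .groups = "drop")
  structure(list(per_image = per_image, per_fold = per_fold,
                 aggregate = aggregate, fold_labels = lab),
            class = "ugb_cv")
}

#' Format a cross-validation aggregate as a percent table
#'
#' One row per metric, `mean +/- sd` in percent with one decimal, the
#' conventional reporting format for segmentation benchmarks.
#' @param cv an `ugb_cv` object.
#' @export
format_cv_table <- function(cv) {
  a <- cv$aggregate
  tibble::tibble(
    metric = a$metric,
    value = sprintf("%.1f ± %.1f", 100 * a$mean, 100 * a$sd))
}

#' @export
print.ugb_cv <- function(x, ...) {
  cat("k-fold cross-validation (", max(x$per_fold$fold), " folds, ",
      nrow(x$per_image), " test images)\n", sep = "")
  print(format_cv_table(x))
  invisible(x)
}

#' @export
print.ugb_fit <- function(x, ...) {
  h <- x$history
  cat("fitted segmentation network: ", length(x$weights), " weight arrays, ",
      nrow(h), " epochs\n", sep = "")
  if (nrow(h)) {
    cat(sprintf("final training loss %.4f, monitored Dice %.3f\n",
                h$loss[nrow(h)], h$dice[nrow(h)]))
  }
  invisible(x)
}
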