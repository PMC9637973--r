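# broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' @param x an `ugb_fit`.
#' @param ... unused.
#' @return the per-epoch history tibble (`epoch`, `loss`, `dice`).
#' @export
tidy.ugb_fit <- function(x, ...) x$history

#' @rdname tidy.ugb_fit
#' @return `glance()`: one-row tibble with epoch count, parameter count and
#'   final loss/Dice.
#' @export
glance.ugb_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    n_parameters = sum(vapply(x$weights, length, integer(1))),
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    final_dice = if (nrow(h)) h$dice[nrow(h)] else NA_real_)
}

#' Tidy a cross-validation result
#'
#' @param x an `ugb_cv`.
#' @param ... unused.
#' @return per-fold tibble in long form (`fold`, `metric`, `value`).
#' @export
tidy.ugb_cv <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold, -"fold",
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.ugb_cv
#' @return `glance()`: one row per metric with across-fold mean and
#'   population standard deviation.
#' @export
glance.ugb_cv <- function(x, ...) {
  tidyr::pivot_wider(x$aggregate, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Training-curve plot
#'
#' Loss and monitored Dice against epoch.
#' @param object an `ugb_fit`.
#' @param ... unused.
#' @export
autoplot.ugb_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "dice"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Cross-validation metric plot
#'
#' Per-fold metric values with the across-fold mean.
#' @param object an `ugb_cv`.
#' @param ... unused.
#' @export
autoplot.ugb_cv <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value", title = "Cross-validation metrics") +
    ggplot2::theme_minimal()
}

#' Display an image sample (and optionally a probability map) as a raster
#'
#' @param object an `image_sample`.
#' @param prob optional probability map overlaid as contour lines at the
#'   0.5 level.
#' @param ... unused.
#' @export
autoplot.image_sample <- function(object, prob = NULL, ...) {
  d <- dim(object$image)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    intensity = as.vector(object$image))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$id, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(prob)) {
    df$prob <- as.vector(prob)
    p <- p + ggplot2::geom_contour(data = df,
                                   ggplot2::aes(z = .data$prob),
                                   breaks = 0.5, colour = "red")
  }
  p
}
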