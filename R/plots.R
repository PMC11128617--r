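# Plot methods -------------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a training history
#'
#' @param object A `seednet_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracy by epoch.
#' @export
autoplot.seednet_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot tile map (rows true class, columns predicted).
#' @export
autoplot.eval_report <- function(object, ...) {
  k <- nrow(object$confusion)
  df <- tidyr::expand_grid(truth = seq_len(k), pred = seq_len(k))
  df$count <- object$confusion[cbind(df$truth, df$pred)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_reverse(breaks = seq_len(k)) +
    ggplot2::scale_x_continuous(breaks = seq_len(k)) +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("Confusion matrix (accuracy %.1f%%)",
                                  100 * object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a class-activation heatmap
#'
#' @param object A `gradcam` matrix from [grad_cam()].
#' @param ... Unused.
#' @return A ggplot raster of the heatmap.
#' @export
autoplot.gradcam <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object)))
  df$value <- object[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "activation") +
    ggplot2::theme_minimal()
}

#' Overlay a heatmap's hot region on its source image
#'
#' Convenience for inspecting where the model looks: returns the image with
#' the top-decile heatmap region tinted.
#'
#' @param image `H x W x 3` array (0..255).
#' @param cam A `gradcam` matrix of the same spatial size.
#' @param quantile Hot-region quantile (default 0.9).
#' @return An `H x W x 3` array (0..255).
#' @export
cam_overlay <- function(image, cam, quantile = 0.9) {
  stopifnot(all(dim(cam) == dim(image)[1:2]))
  hot <- cam >= stats::quantile(cam, quantile)
  out <- image
  r <- out[, , 1]
  r[hot] <- pmin(255, r[hot] + 120)
  out[, , 1] <- r
  out
}
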