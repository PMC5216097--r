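#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training loss curve of a fitted network
#'
#' @param object A fitted `nbi_net`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nbi_net <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy loss",
                  title = "NBI-Net training loss") +
    ggplot2::theme_minimal()
}

#' Plot a vote map as the colored class overlay
#'
#' Covered pixels are painted with the argmax class color (green = A,
#' blue = B1, red = B2_B3); uncovered pixels are blank.
#'
#' @param object An `ipcl_votemap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ipcl_votemap <- function(object, ...) {
  h <- dim(object$scores)[1]; w <- dim(object$scores)[2]
  flat <- matrix(object$scores, h * w, 3)
  cls <- ipcl_classes[max.col(flat, ties.method = "first")]
  cls[as.vector(object$weight_total) == 0] <- NA
  df <- tibble::tibble(x = rep(seq_len(w) - 1, each = h),
                       y = rep(seq_len(h) - 1, times = w),
                       class = cls)
  df <- df[!is.na(df$class), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(A = "green3", B1 = "blue3",
                                          B2_B3 = "red3"), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "type") +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix as a heat map
#'
#' @param object An `ipcl_metrics` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ipcl_metrics <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(ipcl_classes)) +
    ggplot2::labs(title = sprintf("accuracy %.3f (n = %d)",
                                  object$accuracy, object$n)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
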