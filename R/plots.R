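# ggplot2 views of training metrics and salience fields.

#' Plot per-step loss components
#'
#' @param metrics Tibble from [pretrain()] / [read_metrics()].
#' @param components Which columns to draw.
#' @return A ggplot object.
#' @export
plot_metrics <- function(metrics,
                         components = c("mlm", "mim", "itm", "hid", "attn",
                                        "total")) {
  long <- tidyr_longer(metrics, components)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal wide-to-long reshape (avoids a tidyr dependency for one call)
tidyr_longer <- function(df, cols) {
  dplyr::bind_rows(lapply(cols, function(cl) {
    tibble::tibble(step = df$step, component = cl, value = df[[cl]])
  }))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for pre-training results
#' @param object A `pretrain_result`.
#' @param ... Passed to [plot_metrics()].
#' @return A ggplot object.
#' @method autoplot pretrain_result
#' @export
autoplot.pretrain_result <- function(object, ...) {
  plot_metrics(object$metrics, ...)
}

#' Plot a salience field as a patch-grid heat map
#' @param object A `salience_field`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot salience_field
#' @export
autoplot.salience_field <- function(object, ...) {
  N <- length(object$salience)
  grid <- as.integer(round(sqrt(N)))
  df <- tibble::tibble(
    row = rep(seq_len(grid), each = grid),
    col = rep(seq_len(grid), grid),
    salience = object$salience)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$salience)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "salience") +
    ggplot2::theme_minimal()
}
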