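# ggplot2 visualisations for graphs, training and evaluation objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a channel graph's adjacencies
#'
#' Heatmaps of the symmetric base adjacency and, when present, the directed
#' GC-augmented adjacency (row = receiving channel).
#'
#' @param object A [channel_graph()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.channel_graph <- function(object, ...) {
  to_long <- function(m, which) {
    tibble::tibble(
      target = rep(rownames(m), times = ncol(m)),
      source = rep(colnames(m), each = nrow(m)),
      edge = as.vector(m), matrix = which)
  }
  df <- to_long(object$base_adjacency, "base (undirected)")
  if (!is.null(object$gc_adjacency)) {
    df <- dplyr::bind_rows(df, to_long(object$gc_adjacency,
                                       "GC-augmented (directed)"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$source, .data$target,
                                   fill = factor(.data$edge))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_wrap(~matrix) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "steelblue"),
                               name = "edge") +
    ggplot2::labs(x = "source channel", y = "receiving channel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Plot a pretraining loss trajectory
#'
#' @param object An `eeg_checkpoint`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_checkpoint <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("l_s", "l_t", "l_total"),
                            names_to = "loss", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pretraining step", y = "InfoNCE loss") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report's confusion matrix
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy_confusion(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey30", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("Mean CV accuracy %.3f",
                                  object$mean_accuracy)) +
    ggplot2::theme_minimal()
}

#' Bar plot of degree flow (information sources and sinks)
#'
#' @param flow Output of [degree_flow()].
#' @return A ggplot object.
#' @export
plot_degree_flow <- function(flow) {
  df <- dplyr::mutate(flow,
                      role = dplyr::case_when(
                        !is.na(.data$rank_source) & .data$flow > 0 ~ "source",
                        !is.na(.data$rank_sink) & .data$flow < 0 ~ "sink",
                        TRUE ~ "other"))
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$channel, .data$flow),
                                   .data$flow, fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "out-degree minus in-degree") +
    ggplot2::theme_minimal()
}
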