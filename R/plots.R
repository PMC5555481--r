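# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a learned network
#'
#' Nodes on a circle, directed arcs as arrows, undirected edges as plain
#' segments; optional edge labels with bootstrap strength and direction
#' fraction.
#'
#' @param dag a `bn_dag`.
#' @param strengths optional `bn_strength` for edge labels.
#' @return a ggplot object.
#' @export
plot_network <- function(dag, strengths = NULL) {
  d <- length(dag$nodes)
  theta <- seq(0, 2 * pi, length.out = d + 1)[seq_len(d)]
  layout <- tibble::tibble(node = dag$nodes, x = cos(theta), y = sin(theta))
  seg <- dplyr::bind_rows(
    dplyr::mutate(dag$arcs, directed = TRUE),
    dplyr::mutate(dag$undirected, directed = FALSE))
  p <- ggplot2::ggplot(layout, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(seg)) {
    seg <- seg |>
      dplyr::left_join(layout, by = c(from = "node")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(layout, by = c(to = "node")) |>
      dplyr::rename(x1 = "x", y1 = "y") |>
      dplyr::mutate(        # pull segment ends off the node markers
        dx = .data$x1 - .data$x0, dy = .data$y1 - .data$y0,
        len = sqrt(.data$dx^2 + .data$dy^2),
        x0 = .data$x0 + 0.12 * .data$dx / .data$len,
        y0 = .data$y0 + 0.12 * .data$dy / .data$len,
        x1 = .data$x1 - 0.12 * .data$dx / .data$len,
        y1 = .data$y1 - 0.12 * .data$dy / .data$len)
    if (!is.null(strengths)) {
      seg <- seg |>
        dplyr::left_join(strengths$strengths, by = c("from", "to")) |>
        dplyr::mutate(label = sprintf("%.2f (%.2f)", .data$strength, .data$direction))
    }
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linetype = !.data$directed),
      arrow = grid::arrow(length = grid::unit(0.12, "inches"),
                          type = "closed"),
      show.legend = FALSE)
    if (!is.null(strengths)) {
      p <- p + ggplot2::geom_text(
        data = seg,
        ggplot2::aes(x = (.data$x0 + .data$x1) / 2,
                     y = (.data$y0 + .data$y1) / 2, label = .data$label),
        size = 3, vjust = -0.6)
    }
  }
  p + ggplot2::geom_point(size = 10, shape = 21, fill = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$node), size = 3) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}

#' @rdname plot_network
#' @param object a `bn_strength`.
#' @param ... unused.
#' @export
autoplot.bn_strength <- function(object, ...) {
  plot_network(object$averaged, object)
}

#' Heatmap of posterior-mean genomic and residual correlations
#'
#' @param object an `mtm_fit` or `sem_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mtm_fit <- function(object, ...) {
  posterior_correlations(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$trait_1, y = .data$trait_2,
                                 fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f (%.2f)", .data$correlation, .data$sd)), size = 3) +
    ggplot2::facet_wrap(~.data$component) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "correlation")
}

#' Predictive-ability plot
#'
#' Per-trait mean predictive ability with +/- 1 SD bars, by model.
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$ability,
                  ggplot2::aes(x = .data$trait, y = .data$mean,
                               color = .data$model)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "predictive ability (cor(y, y-hat))",
                  color = NULL)
}
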