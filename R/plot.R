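# ggplot2 displays of flow results and selections.

#' Plot the top-ranked nodes of a flow result
#'
#' Horizontal bar chart of the highest-ranked nodes, filled with the
#' subtractive color blend of the per-boundary attributes (see
#' [mix_colors()]): a bar's hue shows which source (or sink) dominates the
#' flow at that node.
#'
#' @param object An `itm_flow`.
#' @param rank_by Ranking attribute (see [ranking_values()]).
#' @param top Number of nodes to show.
#' @param scaling Color scaling function.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itm_flow
#' @export
autoplot.itm_flow <- function(object, rank_by = "total", top = 20,
                              scaling = "sqrt", ...) {
  vals <- ranking_values(object, rank_by)
  sel <- select_nodes(vals, method = "top_k", k = top)
  V <- result_value_matrix(object)
  cc <- as.data.frame(V[sel$node, seq_len(min(3, ncol(V))), drop = FALSE])
  colors <- mix_colors(cbind(tibble(node = sel$node), cc), scaling = scaling)
  df <- dplyr::left_join(sel, colors, by = "node")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$value,
    y = stats::reorder(.data$node, .data$value),
    fill = .data$color
  )) +
    ggplot2::geom_col(color = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(
      x = rank_by,
      y = NULL,
      title = sprintf("%s model, mu = %.3g", object$model, object$mu)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ranked node selection
#'
#' @param object An `itm_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itm_selection
#' @export
autoplot.itm_selection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$value,
    y = stats::reorder(.data$node, .data$value)
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$node),
                          color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "ranking attribute", y = NULL) +
    ggplot2::theme_minimal()
}
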