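# broom-style accessors for flow results.

#' Tidy a flow result into a per-node tibble
#'
#' One row per transient node: the per-boundary attribute columns (visits
#' from each source, or absorption probability to each sink), their `total`,
#' and for emitting/channel results the `interference` (per-node minimum over
#' sources). Rows are ordered by decreasing total, ties by node id.
#'
#' @param x An `itm_flow`.
#' @param ... Unused.
#' @return A tibble with `length(boundary) + 2` (or `+ 3`) columns.
#' @method tidy itm_flow
#' @export
tidy.itm_flow <- function(x, ...) {
  V <- result_value_matrix(x)
  out <- as_tibble(V, rownames = "node")
  out$total <- rowSums(V)
  if (x$model %in% c("emitting", "channel")) {
    out$interference <- apply(V, 1, min)
  }
  dplyr::arrange(out, dplyr::desc(.data$total), .data$node)
}

#' One-row summary of a flow run
#'
#' @param x An `itm_flow`.
#' @param ... Unused.
#' @return A tibble with the model, damping factor, node counts and the
#'   summary statistic (`t_bar` and/or `r_bar`).
#' @method glance itm_flow
#' @export
glance.itm_flow <- function(x, ...) {
  tibble(
    model = x$model,
    mu = x$mu,
    n_nodes = length(x$graph$nodes),
    n_transient = nrow(result_value_matrix(x)),
    n_sources = length(x$sources),
    n_sinks = length(x$sinks),
    n_excluded = length(x$excluded),
    t_bar = x$t_bar %||% NA_real_,
    r_bar = x$r_bar %||% NA_real_
  )
}
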