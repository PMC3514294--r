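# The damped random-walk evolution operator P = mu * D^-1 W.

#' Build the damped evolution operator
#'
#' Row-normalizes the weight matrix and folds in the damping factor:
#' `P[i, j] = mu * W[i, j] / sum_j' W[i, j']`. Every node with at least one
#' outgoing weight has row sum exactly `mu`, i.e. a per-step dissipation
#' probability of `1 - mu`. Dangling nodes (zero out-weight) and excluded
#' nodes have identically zero rows: a walker arriving there is lost.
#'
#' @param graph An `itm_graph`.
#' @param mu Damping factor in `[0, 1]`: the per-step survival probability of
#'   a walker.
#' @param sources,sinks Character vectors of boundary node ids. Sources form
#'   the emitting boundary (walks terminate on return), sinks the absorbing
#'   boundary. Which sets are required depends on the model being solved.
#' @return An `itm_operator` holding `P` (sparse, row-substochastic), `mu`,
#'   the node ordering and the boundary bookkeeping.
#' @examples
#' g <- make_fixture("path", 3)
#' op <- evolution_operator(g, mu = 0.9, sources = "a", sinks = "c")
#' Matrix::rowSums(op$P) # 0.9 for every node with out-edges
#' @export
evolution_operator <- function(graph, mu, sources = character(),
                               sinks = character()) {
  stopifnot(inherits(graph, "itm_graph"))
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0 || mu > 1) {
    abort_validation("`mu` must be a single number in [0, 1].")
  }
  sources <- as.character(sources)
  sinks <- as.character(sinks)
  unknown <- setdiff(c(sources, sinks), graph$nodes)
  if (length(unknown) > 0) {
    abort_validation(paste0(
      "Boundary node(s) not in graph: ", paste(unknown, collapse = ", ")
    ))
  }
  overlap <- intersect(sources, sinks)
  if (length(overlap) > 0) {
    abort_validation(paste0(
      "Node(s) cannot be both source and sink: ",
      paste(overlap, collapse = ", ")
    ))
  }
  in_excl <- intersect(c(sources, sinks), graph$excluded)
  if (length(in_excl) > 0) {
    abort_validation(paste0(
      "Boundary node(s) are excluded: ", paste(in_excl, collapse = ", ")
    ))
  }
  rs <- rowSums(graph$W)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  P <- mu * Diagonal(x = inv) %*% graph$W
  P <- methods::as(P, "CsparseMatrix")
  dimnames(P) <- list(graph$nodes, graph$nodes)
  structure(
    list(P = P, mu = mu, nodes = graph$nodes, sources = sources,
         sinks = sinks, excluded = graph$excluded, graph = graph),
    class = "itm_operator"
  )
}

#' @export
print.itm_operator <- function(x, ...) {
  cat(sprintf(
    "<itm_operator> %d nodes, mu = %g, %d source(s), %d sink(s), %d excluded\n",
    length(x$nodes), x$mu, length(x$sources), length(x$sinks),
    length(x$excluded)
  ))
  invisible(x)
}

# transient node set for a given model
transient_nodes <- function(op, model) {
  boundary <- switch(model,
    emitting = op$sources,
    absorbing = op$sinks,
    channel = c(op$sources, op$sinks)
  )
  setdiff(op$nodes, c(boundary, op$excluded))
}
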