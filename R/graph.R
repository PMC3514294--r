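# Weighted directed graph construction: typed raw edges -> collapsed W matrix.

#' Edge-type directionality policy
#'
#' Interaction networks carry typed edges (e.g. `"pp"`, `"pd"`), and each type
#' must be treated as directed, undirected, or ignored before a random-walk
#' substrate can be built. Types not listed in either `directed` or `ignored`
#' are undirected by default, matching the convention that a freshly loaded
#' network starts with every edge type bidirectional.
#'
#' @param directed Character vector of edge types taken as one-way: the edge
#'   weight applies only in the recorded source-to-target direction.
#' @param ignored Character vector of edge types dropped entirely (zero weight
#'   in both directions).
#' @return An object of class `itm_policy`.
#' @examples
#' edge_policy(directed = "pd", ignored = "sibling")
#' @export
edge_policy <- function(directed = character(), ignored = character()) {
  directed <- as.character(directed)
  ignored <- as.character(ignored)
  dup <- intersect(directed, ignored)
  if (length(dup) > 0) {
    abort_validation(paste0(
      "Edge types assigned to more than one category: ",
      paste(dup, collapse = ", ")
    ))
  }
  structure(list(directed = directed, ignored = ignored),
            class = "itm_policy")
}

edge_category <- function(etype, policy) {
  dplyr::case_when(
    etype %in% policy$ignored ~ "ignored",
    etype %in% policy$directed ~ "directed",
    .default = "undirected"
  )
}

validate_raw_edges <- function(edges) {
  if (!is.data.frame(edges)) {
    abort_validation("`edges` must be a data frame of raw edges.")
  }
  required <- c("source", "target")
  missing <- setdiff(required, names(edges))
  if (length(missing) > 0) {
    abort_validation(paste0(
      "Edge table is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  edges <- as_tibble(edges)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (!"etype" %in% names(edges)) edges$etype <- "edge"
  edges$etype <- as.character(edges$etype)
  if (!"weight" %in% names(edges)) edges$weight <- NA_real_
  edges$weight <- as.numeric(edges$weight)
  bad_id <- !nzchar(edges$source) | !nzchar(edges$target) |
    is.na(edges$source) | is.na(edges$target)
  if (any(bad_id)) {
    abort_validation(paste0(
      "Edge(s) with empty or missing node ids at row(s): ",
      paste(which(bad_id), collapse = ", ")
    ))
  }
  neg <- which(!is.na(edges$weight) & edges$weight < 0)
  if (length(neg) > 0) {
    e <- edges[neg[1], ]
    abort_validation(sprintf(
      "Negative edge weight (%g) on edge %s -> %s (type '%s').",
      e$weight, e$source, e$target, e$etype
    ))
  }
  edges
}

#' Resolve edge weights from the weighting mode
#'
#' Two weighting modes exist. In `"default"` mode (no weight attribute is
#' available) every self-loop receives weight 2 and every other edge weight 1.
#' In `"attribute"` mode the `weight` column is used as-is and missing (`NA`)
#' values are treated as zero weight, so those edges vanish when the graph is
#' collapsed.
#'
#' @param edges Data frame with columns `source`, `target`, optional `etype`
#'   and `weight`.
#' @param mode `"default"` or `"attribute"`.
#' @return The edge tibble with a fully resolved numeric `weight` column.
#' @examples
#' edges <- tibble::tibble(source = c("a", "a"), target = c("a", "b"))
#' apply_default_weights(edges, mode = "default")
#' @export
apply_default_weights <- function(edges, mode = c("default", "attribute")) {
  mode <- rlang::arg_match(mode)
  edges <- validate_raw_edges(edges)
  if (mode == "default") {
    edges$weight <- ifelse(edges$source == edges$target, 2, 1)
  } else {
    edges$weight <- ifelse(is.na(edges$weight), 0, edges$weight)
  }
  edges
}

#' Collapse typed multi-edges into a weighted digraph
#'
#' Multiple edges between the same pair of nodes are merged by summing their
#' weights per direction. Undirected edges contribute their weight to both
#' directions; directed edges only forward; ignored types contribute nothing.
#' A self-loop contributes its weight once regardless of category (forward and
#' backward coincide). Entries that sum to zero are dropped, so all stored
#' weights are strictly positive.
#'
#' @param edges Data frame of raw edges with resolved nonnegative weights
#'   (see [apply_default_weights()]).
#' @param policy An [edge_policy()].
#' @return An `itm_graph`: node set (lexicographically ordered), sparse weight
#'   matrix `W`, and an (initially empty) excluded-node set.
#' @examples
#' edges <- tibble::tibble(
#'   source = c("A", "B", "A"), target = c("B", "A", "B"),
#'   etype = c("I", "I", "II"), weight = c(2, 5, 1)
#' )
#' g <- collapse_edges(edges, edge_policy(directed = "I"))
#' igraph_weight(g, "A", "B") # 3
#' igraph_weight(g, "B", "A") # 6
#' @export
collapse_edges <- function(edges, policy = edge_policy()) {
  edges <- validate_raw_edges(edges)
  if (any(is.na(edges$weight))) {
    abort_validation(
      "Unresolved (missing) edge weights; call apply_default_weights() first."
    )
  }
  if (!inherits(policy, "itm_policy")) {
    abort_validation("`policy` must be created by edge_policy().")
  }
  # every node mentioned in the raw table is a graph node, even if all of its
  # edges are ignored or zero-weight
  nodes <- sort(unique(c(edges$source, edges$target)), method = "radix")

  edges$category <- edge_category(edges$etype, policy)
  kept <- dplyr::filter(edges, .data$category != "ignored")
  fwd <- dplyr::transmute(kept, from = .data$source, to = .data$target,
                          weight = .data$weight)
  bwd <- kept |>
    dplyr::filter(.data$category == "undirected",
                  .data$source != .data$target) |>
    dplyr::transmute(from = .data$target, to = .data$source,
                     weight = .data$weight)
  collapsed <- dplyr::bind_rows(fwd, bwd) |>
    dplyr::summarise(weight = sum(.data$weight),
                     .by = c("from", "to")) |>
    dplyr::filter(.data$weight > 0)

  W <- sparseMatrix(
    i = match(collapsed$from, nodes),
    j = match(collapsed$to, nodes),
    x = collapsed$weight,
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes)
  )
  new_itm_graph(nodes = nodes, W = W, excluded = character())
}

new_itm_graph <- function(nodes, W, excluded) {
  structure(list(nodes = nodes, W = W, excluded = excluded),
            class = "itm_graph")
}

#' Build a flow graph from a raw edge table
#'
#' One-stop constructor chaining weight resolution ([apply_default_weights()]),
#' multi-edge collapsing ([collapse_edges()]) and excluded-node marking
#' ([exclude_nodes()]). With `weight_mode = "auto"`, attribute mode is used
#' when the table has a `weight` column containing at least one non-missing
#' value, default mode otherwise.
#'
#' @inheritParams collapse_edges
#' @param weight_mode `"auto"`, `"default"` or `"attribute"`.
#' @param excluded Character vector of node ids at which all arriving flow is
#'   dissipated.
#' @return An `itm_graph`.
#' @export
flow_graph <- function(edges, policy = edge_policy(),
                       weight_mode = c("auto", "default", "attribute"),
                       excluded = character()) {
  weight_mode <- rlang::arg_match(weight_mode)
  edges <- validate_raw_edges(edges)
  if (weight_mode == "auto") {
    weight_mode <- if (any(!is.na(edges$weight))) "attribute" else "default"
  }
  edges <- apply_default_weights(edges, mode = weight_mode)
  g <- collapse_edges(edges, policy)
  exclude_nodes(g, excluded)
}

#' Mark nodes as excluded (full dissipation)
#'
#' Any flow reaching an excluded node is fully dissipated: the node keeps its
#' incoming edges (so neighbours still lose probability into it) but all its
#' outgoing entries are removed. This models nodes that should not relay
#' information, e.g. promiscuous hubs creating biologically implausible
#' shortcuts. Excluding a node is therefore not the same as deleting it, which
#' would silently redistribute the flow among the surviving neighbours.
#'
#' @param graph An `itm_graph`.
#' @param excluded Character vector of node ids to exclude.
#' @return The graph with zeroed outgoing rows for the excluded nodes.
#' @export
exclude_nodes <- function(graph, excluded) {
  stopifnot(inherits(graph, "itm_graph"))
  excluded <- as.character(excluded)
  if (length(excluded) == 0) return(graph)
  unknown <- setdiff(excluded, graph$nodes)
  if (length(unknown) > 0) {
    abort_validation(paste0(
      "Excluded node(s) not in graph: ", paste(unknown, collapse = ", ")
    ))
  }
  excluded <- union(graph$excluded, excluded)
  W <- graph$W
  W[match(excluded, graph$nodes), ] <- 0
  W <- Matrix::drop0(W)
  new_itm_graph(nodes = graph$nodes, W = W, excluded = excluded)
}

#' Look up a single collapsed edge weight
#'
#' @param graph An `itm_graph`.
#' @param from,to Node ids.
#' @return The collapsed weight of `from -> to` (0 if absent).
#' @export
igraph_weight <- function(graph, from, to) {
  stopifnot(inherits(graph, "itm_graph"))
  if (!from %in% graph$nodes || !to %in% graph$nodes) return(0)
  as.numeric(graph$W[from, to])
}

#' @export
print.itm_graph <- function(x, ...) {
  cat(sprintf(
    "<itm_graph> %d nodes, %d directed weighted edges, %d excluded\n",
    length(x$nodes), Matrix::nnzero(x$W), length(x$excluded)
  ))
  invisible(x)
}

#' @describeIn flow_graph Edge list of the collapsed graph as a tibble with
#'   columns `from`, `to`, `weight`.
#' @param x An `itm_graph`.
#' @param ... Unused.
#' @method tidy itm_graph
#' @export
tidy.itm_graph <- function(x, ...) {
  TW <- methods::as(methods::as(x$W, "generalMatrix"), "TsparseMatrix")
  tibble(
    from = x$nodes[TW@i + 1L],
    to = x$nodes[TW@j + 1L],
    weight = TW@x
  ) |>
    dplyr::arrange(.data$from, .data$to)
}

# convert to an igraph object for connectivity / shortest-path queries
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$W, mode = "directed",
                                      weighted = TRUE)
}

# hop-count shortest path from any of `from` to any of `to`; Inf if none
shortest_hops <- function(graph, from, to) {
  g <- as_igraph(graph)
  d <- igraph::distances(g, v = from, to = to, mode = "out", weights = NA)
  min(d)
}

# node ids with a directed positive-weight path to at least one of `sinks`
reachable_to <- function(graph, sinks) {
  g <- as_igraph(graph)
  d <- igraph::distances(g, v = sinks, to = igraph::V(g), mode = "in",
                         weights = NA)
  graph$nodes[apply(is.finite(d), 2, any)]
}
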