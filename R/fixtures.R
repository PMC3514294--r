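# Deterministic fixture graphs for tests, examples and benchmarking.

path_node_names <- function(size) {
  if (size <= 26) letters[seq_len(size)] else sprintf("v%03d", seq_len(size))
}

#' Generate a fixture graph
#'
#' Small deterministic graphs covering the structures the flow models are
#' exercised on:
#' \describe{
#'   \item{`path`}{an undirected chain `a - b - c - ...` of `size` nodes with
#'     unit weights; closed-form solutions exist for small sizes.}
#'   \item{`parallel_paths`}{a source `s` and sink `t` joined by two disjoint
#'     undirected arms with `arms[1]` and `arms[2]` internal nodes; with
#'     unequal arms the shorter one is the unique shortest path
#'     (`min(arms) + 1` hops).}
#'   \item{`lattice_with_holes`}{a `size x size` undirected square lattice
#'     with 10% of nodes and then 10% of the remaining edges removed
#'     uniformly at random — an irregular planar mesh.}
#'   \item{`random_er`}{a connected Erdos-Renyi graph on `size` nodes with
#'     edge probability `min(1, 1.5 log(size)/size)`; disconnected draws are
#'     rejected and regenerated with an incremented seed (reported via a
#'     message).}
#' }
#' All fixtures use unit edge weights and a single undirected edge type, and
#' are byte-reproducible for a given `seed`.
#'
#' @param kind Fixture family.
#' @param size Node count (`path`, `random_er`) or lattice side; defaults per
#'   kind (3, 30, 6).
#' @param seed RNG seed for the random kinds.
#' @param arms Internal node counts of the two `parallel_paths` arms.
#' @return An `itm_graph`.
#' @examples
#' make_fixture("path", 3) # the a-b-c chain
#' @export
make_fixture <- function(kind = c("path", "parallel_paths",
                                  "lattice_with_holes", "random_er"),
                         size = NULL, seed = 1L, arms = c(2, 5)) {
  kind <- rlang::arg_match(kind)
  size <- size %||% switch(kind, path = 3L, parallel_paths = NA_integer_,
                           lattice_with_holes = 6L, random_er = 30L)
  edges <- switch(kind,
    path = {
      if (size < 2) abort_validation("A path fixture needs size >= 2.")
      ids <- path_node_names(size)
      tibble(source = ids[-size], target = ids[-1], etype = "u")
    },
    parallel_paths = {
      if (length(arms) != 2 || any(arms < 1)) {
        abort_validation("`arms` must give two internal node counts >= 1.")
      }
      arm <- function(tag, len) {
        ids <- sprintf("%s%02d", tag, seq_len(len))
        tibble(source = c("s", ids), target = c(ids, "t"), etype = "u")
      }
      dplyr::bind_rows(arm("p", arms[1]), arm("q", arms[2]))
    },
    lattice_with_holes = {
      if (size < 3) abort_validation("A lattice fixture needs size >= 3.")
      withr::local_seed(seed)
      ids <- outer(seq_len(size), seq_len(size),
                   function(i, j) sprintf("n%02d_%02d", i, j))
      horiz <- tibble(source = as.vector(ids[, -size]),
                      target = as.vector(ids[, -1]), etype = "u")
      vert <- tibble(source = as.vector(ids[-size, ]),
                     target = as.vector(ids[-1, ]), etype = "u")
      ed <- dplyr::bind_rows(horiz, vert)
      drop_nodes <- sample(as.vector(ids), floor(0.1 * length(ids)))
      ed <- dplyr::filter(ed, !.data$source %in% drop_nodes,
                          !.data$target %in% drop_nodes)
      ed[-sample(nrow(ed), floor(0.1 * nrow(ed))), ]
    },
    random_er = {
      if (size < 2) abort_validation("A random fixture needs size >= 2.")
      p <- min(1, 1.5 * log(size) / size)
      ids <- path_node_names(size)
      attempt <- seed
      repeat {
        withr::local_seed(attempt)
        pairs <- utils::combn(ids, 2)
        pick <- runif(ncol(pairs)) < p
        ed <- tibble(source = pairs[1, pick], target = pairs[2, pick],
                     etype = "u")
        g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                           vertices = ids)
        if (igraph::is_connected(g)) break
        inform(sprintf("random_er draw with seed %d disconnected; retrying.",
                       attempt))
        attempt <- attempt + 1L
        if (attempt - seed > 50) abort("Could not draw a connected graph.")
      }
      ed
    }
  )
  flow_graph(edges, weight_mode = "default")
}
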