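# Graph construction: weighting modes, edge collapsing, exclusion semantics.

test_that("typed multi-edges collapse by summing weights per direction", {
  edges <- raw_edges(
    ~source, ~target, ~etype, ~weight,
    "A", "B", "I", 2,
    "B", "A", "I", 5,
    "A", "B", "II", 1
  )
  g <- collapse_edges(edges, edge_policy(directed = "I"))
  expect_equal(igraph_weight(g, "A", "B"), 3)
  expect_equal(igraph_weight(g, "B", "A"), 6)

  sym <- collapse_edges(
    raw_edges(~source, ~target, ~etype, ~weight, "A", "B", "u", 4),
    edge_policy()
  )
  expect_equal(igraph_weight(sym, "A", "B"), 4)
  expect_equal(igraph_weight(sym, "B", "A"), 4)

  ignored <- collapse_edges(
    raw_edges(~source, ~target, ~etype, ~weight, "A", "B", "skip", 7),
    edge_policy(ignored = "skip")
  )
  expect_equal(Matrix::nnzero(ignored$W), 0)
  expect_setequal(ignored$nodes, c("A", "B")) # nodes survive, weights do not
})

test_that("collapsing is order-independent and undirected graphs symmetric", {
  edges <- raw_edges(
    ~source, ~target, ~etype, ~weight,
    "n1", "n2", "u", 1,
    "n2", "n3", "u", 2,
    "n1", "n3", "d", 3,
    "n3", "n3", "u", 2,
    "n2", "n1", "d", 0.5
  )
  g1 <- collapse_edges(edges, edge_policy(directed = "d"))
  for (perm_seed in 1:3) {
    withr::with_seed(perm_seed, {
      g2 <- collapse_edges(edges[sample(nrow(edges)), ],
                           edge_policy(directed = "d"))
    })
    expect_identical(g1$nodes, g2$nodes)
    expect_equal(as.matrix(g1$W), as.matrix(g2$W))
  }

  und <- collapse_edges(dplyr::filter(edges, etype == "u"), edge_policy())
  expect_equal(as.matrix(und$W), t(as.matrix(und$W)))
})

test_that("default-weight mode gives self-loops 2 and other edges 1", {
  edges <- raw_edges(
    ~source, ~target, ~etype, ~weight,
    "a", "a", "u", NA,
    "a", "b", "u", NA
  )
  resolved <- apply_default_weights(edges, mode = "default")
  expect_equal(resolved$weight, c(2, 1))

  g <- flow_graph(edges, weight_mode = "default")
  expect_equal(igraph_weight(g, "a", "a"), 2)
  expect_equal(igraph_weight(g, "a", "b"), 1)
})

test_that("attribute mode treats missing weights as zero and drops the edge", {
  edges <- raw_edges(
    ~source, ~target, ~etype, ~weight,
    "a", "b", "u", NA,
    "b", "c", "u", 1.5
  )
  resolved <- apply_default_weights(edges, mode = "attribute")
  expect_equal(resolved$weight, c(0, 1.5))
  g <- flow_graph(edges, weight_mode = "attribute")
  expect_equal(igraph_weight(g, "a", "b"), 0)
  expect_equal(igraph_weight(g, "b", "c"), 1.5)
  # auto mode picks attribute mode when any weight is present
  g_auto <- flow_graph(edges)
  expect_equal(as.matrix(g_auto$W), as.matrix(g$W))
})

test_that("negative weights and malformed ids are rejected with context", {
  expect_error(
    collapse_edges(raw_edges(~source, ~target, ~etype, ~weight,
                             "a", "b", "u", -1)),
    "a -> b", class = "itm_validation_error"
  )
  expect_error(
    flow_graph(tibble::tibble(source = "", target = "b")),
    "empty", class = "itm_validation_error"
  )
})

test_that("excluded nodes lose outgoing flow but keep incoming entries", {
  g <- flow_graph(raw_edges(
    ~source, ~target, ~etype, ~weight,
    "a", "b", "u", NA,
    "b", "x", "u", NA
  ), weight_mode = "default")
  gx <- exclude_nodes(g, "x")
  expect_equal(igraph_weight(gx, "x", "b"), 0) # out-degree zero
  expect_equal(igraph_weight(gx, "b", "x"), 1) # denominator still counts x
  expect_equal(igraph_weight(gx, "b", "a"), igraph_weight(g, "b", "a"))

  # on a longer path a-b-c-x, walkers at c still step into x and die there,
  # so b and c see fewer revisits than if x were deleted outright (deletion
  # would redistribute c's flow back toward b instead of dissipating it)
  chain <- raw_edges(
    ~source, ~target, ~etype, ~weight,
    "a", "b", "u", NA,
    "b", "c", "u", NA,
    "c", "x", "u", NA
  )
  res_excl <- itm_flow(
    exclude_nodes(flow_graph(chain, weight_mode = "default"), "x"),
    "emitting", sources = "a", mu = 0.9
  )
  res_del <- itm_flow(
    flow_graph(chain[1:2, ], weight_mode = "default"),
    "emitting", sources = "a", mu = 0.9
  )
  expect_lt(res_excl$H["a", "b"], res_del$H["a", "b"])
  expect_lt(res_excl$H["a", "c"], res_del$H["a", "c"])

  expect_identical(exclude_nodes(g, character()), g)
  expect_error(exclude_nodes(g, "zz"), "not in graph",
               class = "itm_validation_error")
  expect_error(
    evolution_operator(exclude_nodes(g, "x"), 0.5, sources = "x"),
    "excluded", class = "itm_validation_error"
  )
})

test_that("excluded-node dissipation matches the Monte Carlo walker rule", {
  # path a-b-x with x excluded: a walker at b steps to a or x with equal
  # probability and dies at x, so H[a,b] from the solver must match the
  # simulated mean visit count
  g <- exclude_nodes(flow_graph(raw_edges(
    ~source, ~target, ~etype, ~weight,
    "a", "b", "u", NA,
    "b", "x", "u", NA
  ), weight_mode = "default"), "x")
  res <- itm_flow(g, "emitting", sources = "a", mu = 0.8)
  sim <- simulate_walks(g, "emitting", mu = 0.8, sources = "a",
                        n_walkers = 40000, seed = 11)
  est <- sim$visits_by_source["a", "b"]
  se <- sim$visits_by_source_se["a", "b"]
  expect_lt(abs(est - res$H["a", "b"]), 4 * se)
})
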