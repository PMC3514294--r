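# The three flow models against closed forms, conservation laws and limits.

test_that("evolution operator rows are mu-normalized weight fractions", {
  g <- path3()
  op <- evolution_operator(g, 0.9, sources = "a", sinks = "c")
  expect_equal(as.numeric(op$P["b", "a"]), 0.45)
  expect_equal(as.numeric(op$P["b", "c"]), 0.45)
  expect_equal(as.numeric(op$P["a", "b"]), 0.9)
  # every node with out-edges leaks exactly 1 - mu in one step
  expect_equal(unname(Matrix::rowSums(op$P)), rep(0.9, 3))

  expect_true(all(as.matrix(evolution_operator(g, 0)$P) == 0))
  expect_error(evolution_operator(g, 1.2), class = "itm_validation_error")
  expect_error(evolution_operator(g, 0.5, sources = "a", sinks = "a"),
               "both source and sink", class = "itm_validation_error")
})

test_that("absorbing model reproduces the hand-solved 2x2 system", {
  res <- solve_absorbing(evolution_operator(path3(), 0.9, sinks = "c"))
  expect_equal(res$F["a", "c"], ref_path3$F_ac, tolerance = 1e-12)
  expect_equal(res$F["b", "c"], ref_path3$F_bc, tolerance = 1e-12)
  expect_equal(res$r_bar, ref_path3$r_bar, tolerance = 1e-12)
})

test_that("without damping all absorption probabilities sum to one", {
  res <- solve_absorbing(evolution_operator(path3(), 1, sinks = "c"))
  expect_equal(unname(rowSums(res$F)), c(1, 1), tolerance = 1e-10)
  expect_equal(res$r_bar, 1, tolerance = 1e-10)

  # two sinks on a connected random graph: still conservative
  er <- make_fixture("random_er", 20, seed = 4)
  sinks <- er$nodes[c(1, 10)]
  res2 <- solve_absorbing(evolution_operator(er, 1, sinks = sinks))
  expect_true(all(abs(rowSums(res2$F) - 1) < 1e-10))
})

test_that("transient nodes cut off from every sink get a zero row, and a
           damping-free solve on such a graph is refused", {
  # two components: a-b and c-d; sink d is unreachable from a and b
  g <- flow_graph(raw_edges(
    ~source, ~target, ~etype, ~weight,
    "a", "b", "u", NA,
    "c", "d", "u", NA
  ), weight_mode = "default")
  res <- solve_absorbing(evolution_operator(g, 0.5, sinks = "d"))
  expect_equal(unname(res$F[c("a", "b"), "d"]), c(0, 0))
  # r_bar averages only over sink-connected transient nodes
  expect_equal(res$r_bar, res$F["c", "d"])

  expect_error(solve_absorbing(evolution_operator(g, 1, sinks = "d")),
               "a, b")
})

test_that("emitting model reproduces the hand-solved visit counts", {
  res <- solve_emitting(evolution_operator(path3(), 0.9, sources = "a"))
  expect_equal(res$H["a", "b"], ref_path3$H_ab, tolerance = 1e-12)
  expect_equal(res$H["a", "c"], ref_path3$H_ac, tolerance = 1e-12)
  expect_equal(res$t_bar, ref_path3$t_bar, tolerance = 1e-12)
  # visit counts exceed 1 where walkers revisit
  expect_gt(res$H["a", "b"], 1)

  expect_error(solve_emitting(evolution_operator(path3(), 1, sources = "a")),
               class = "itm_validation_error")
  expect_error(solve_emitting(evolution_operator(path3(), 0.9)),
               class = "itm_validation_error")
})

test_that("degenerate damping endpoints behave as documented", {
  expect_warning(
    res <- solve_emitting(evolution_operator(path3(), 0, sources = "a")),
    "mu = 0"
  )
  expect_true(all(res$H == 0))
  expect_equal(res$t_bar, 1)
  expect_warning(
    resa <- solve_absorbing(evolution_operator(path3(), 0, sinks = "c")),
    "mu = 0"
  )
  expect_true(all(resa$F == 0))
  # a source with no out-edges emits walkers that die on the first move
  g <- flow_graph(raw_edges(~source, ~target, ~etype, ~weight,
                            "a", "b", "d", NA),
                  policy = edge_policy(directed = "d"),
                  weight_mode = "default")
  res_b <- solve_emitting(evolution_operator(g, 0.9, sources = "b"))
  expect_equal(res_b$t_bar, 1)
})

test_that("channel model normalizes single-path flow to unit visits", {
  for (mu in c(0.05, 0.3, 0.9, 0.999)) {
    res <- solve_channel(
      evolution_operator(path3(), mu, sources = "a", sinks = "c")
    )
    expect_equal(unname(res$Phi_hat["a", "b"]), 1, tolerance = 1e-10)
    expect_equal(res$t_bar, 2, tolerance = 1e-10)
  }
})

test_that("strong damping confines the channel to the shortest path", {
  pp <- make_fixture("parallel_paths", arms = c(2, 5))
  res <- solve_channel(evolution_operator(pp, 0.01, sources = "s", sinks = "t"))
  on_path <- c("p01", "p02")
  off_path <- setdiff(colnames(res$Phi_hat), on_path)
  expect_true(all(abs(res$Phi_hat["s", on_path] - 1) < 1e-3))
  expect_lt(sum(res$Phi_hat["s", off_path]), 1e-3)
  # channel mean path length never undercuts the shortest-path hop count
  for (mu in c(0.05, 0.5, 0.95)) {
    r <- solve_channel(evolution_operator(pp, mu, sources = "s", sinks = "t"))
    expect_gte(r$t_bar, 3 - 1e-12)
  }
})

test_that("sinks split channel flow by proximity to the source", {
  # source at one end of a 5-path, sinks at distance 2 and 4
  g <- make_fixture("path", 5)
  res <- solve_channel(
    evolution_operator(g, 0.7, sources = "a", sinks = c("c", "e"))
  )
  f <- res$F_sources["a", ]
  expect_gt(f[["c"]], f[["e"]])
  expect_error(
    solve_channel(evolution_operator(
      flow_graph(raw_edges(~source, ~target, ~etype, ~weight,
                           "a", "b", "d", NA, "c", "b", "d", NA),
                 policy = edge_policy(directed = "d"),
                 weight_mode = "default"),
      0.5, sources = "c", sinks = "a"
    )),
    "c" # the stranded source is named
  )
})

test_that("interference peaks strictly between two opposing sources", {
  g <- make_fixture("path", 5)
  res <- solve_emitting(evolution_operator(g, 0.9, sources = c("a", "e")))
  intf <- interference(res)
  expect_setequal(names(intf), c("b", "c", "d"))
  expect_equal(names(which.max(intf)), "c")
  expect_equal(intf, pmin(res$H["a", ], res$H["e", ]))
  # single source: interference is that source's row
  res1 <- solve_emitting(evolution_operator(g, 0.9, sources = "a"))
  expect_equal(interference(res1), res1$H["a", ])
})

test_that("summary statistics are monotone in the damping factor", {
  er <- make_fixture("random_er", 15, seed = 9)
  src <- er$nodes[3]
  snk <- er$nodes[c(8, 12)]
  mus <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  t_bars <- vapply(mus, function(m) {
    solve_emitting(evolution_operator(er, m, sources = src))$t_bar
  }, numeric(1))
  expect_true(all(diff(t_bars) > 0))
  r_bars <- vapply(c(mus, 1), function(m) {
    solve_absorbing(evolution_operator(er, m, sinks = snk))$r_bar
  }, numeric(1))
  expect_true(all(diff(r_bars) > 0))
})

test_that("linear-solve residuals stay below 1e-9", {
  er <- make_fixture("random_er", 25, seed = 6)
  expect_lt(solve_residual(er, "absorbing", 0.9, sinks = er$nodes[1:2]), 1e-9)
  expect_lt(solve_residual(er, "emitting", 0.9, sources = er$nodes[5]), 1e-9)
  expect_lt(
    solve_residual(er, "channel", 0.9, sources = er$nodes[5],
                   sinks = er$nodes[1:2]),
    1e-9
  )
})

test_that("absorbing and emitting views agree through the degree-weighted
           duality on undirected graphs", {
  # for an undirected graph with uniform damping, F[i -> k] equals
  # H[k -> i] * deg(k) / deg(i); spot-checked numerically
  er <- make_fixture("random_er", 12, seed = 3)
  k <- er$nodes[4]
  deg <- Matrix::rowSums(er$W)
  Fik <- solve_absorbing(evolution_operator(er, 0.8, sinks = k))$F[, k]
  Hki <- solve_emitting(evolution_operator(er, 0.8, sources = k))$H[k, ]
  expect_equal(Fik, Hki * deg[[k]] / deg[names(Fik)], tolerance = 1e-9)
})

test_that("raw channel visits factorize into emitting and absorbing parts", {
  g <- make_fixture("path", 5)
  res <- solve_channel(evolution_operator(g, 0.6, sources = "a", sinks = "e"))
  phi <- raw_phi(res)
  expect_equal(phi$phi,
               res$H[cbind(phi$source, phi$node)] *
                 res$F[cbind(phi$node, phi$sink)])
})
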