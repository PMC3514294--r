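# Shared fixtures and closed-form reference values.
#
# On the 3-node undirected unit-weight path a-b-c with mu = 0.9 the transient
# systems are 2x2 and solvable by hand:
#   absorbing, sink c:   F[a,c] = 0.81/1.19, F[b,c] = 0.9/1.19
#   emitting, source a:  H[a,b] = 0.9/0.595, H[a,c] = 0.405/0.595
# from which t_bar = 1 + H[a,b] + H[a,c] and r_bar = (F[a,c] + F[b,c]) / 2.

path3 <- function() make_fixture("path", 3)

ref_path3 <- list(
  F_ac = 0.81 / 1.19,
  F_bc = 0.9 / 1.19,
  H_ab = 0.9 / 0.595,
  H_ac = 0.405 / 0.595,
  t_bar = 1 + 0.9 / 0.595 + 0.405 / 0.595,
  r_bar = (0.81 / 1.19 + 0.9 / 1.19) / 2
)

raw_edges <- function(...) {
  tibble::tribble(...)
}

# max |(I - P_TT) x - b| over the solved system, recomputed from the result
solve_residual <- function(graph, model, mu, sources = character(),
                           sinks = character()) {
  op <- evolution_operator(graph, mu, sources = sources, sinks = sinks)
  res <- switch(model,
    absorbing = solve_absorbing(op),
    emitting = solve_emitting(op),
    channel = solve_channel(op)
  )
  transient <- switch(model,
    absorbing = rownames(res$F),
    emitting = colnames(res$H),
    channel = colnames(res$H)
  )
  idxT <- match(transient, op$nodes)
  A <- Matrix::Diagonal(length(idxT)) - op$P[idxT, idxT, drop = FALSE]
  if (model == "absorbing") {
    B <- op$P[idxT, match(res$sinks, op$nodes), drop = FALSE]
    max(abs(A %*% res$F - B))
  } else {
    B <- Matrix::t(op$P[match(res$sources, op$nodes), idxT, drop = FALSE])
    max(abs(Matrix::t(A) %*% t(res$H) - B))
  }
}
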