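# Sparse linear solves for the emitting, absorbing and channel flow models.
#
# All three models reduce to the fundamental-matrix identity of absorbing
# Markov chains: with P_TT the restriction of the evolution operator to
# transient nodes and G = (I - P_TT)^-1,
#   F[i, k] = (G P_TK)[i, k]   absorption probability at sink k from i,
#   H[s, i] = (P_ST G)[s, i]   expected visits to i per walker emitted at s.
# G is never formed: each model performs one sparse LU solve of (I - P_TT)
# (or its transpose) against a narrow block of right-hand sides.

new_itm_flow <- function(model, mu, sources, sinks, excluded, graph,
                         H = NULL, F = NULL, Phi_hat = NULL,
                         t_bar = NULL, r_bar = NULL, criterion = NULL,
                         custom = list()) {
  structure(
    list(model = model, mu = mu, sources = sources, sinks = sinks,
         excluded = excluded, graph = graph, H = H, F = F,
         Phi_hat = Phi_hat, t_bar = t_bar, r_bar = r_bar,
         criterion = criterion, custom = custom),
    class = "itm_flow"
  )
}

# I - P_TT as a sparse matrix over the transient index set
transient_system <- function(op, transient) {
  idx <- match(transient, op$nodes)
  A <- Diagonal(length(idx)) - op$P[idx, idx, drop = FALSE]
  methods::as(A, "CsparseMatrix")
}

dense <- function(M, rows, cols) {
  M <- as.matrix(M)
  dimnames(M) <- list(rows, cols)
  M
}

#' Solve the absorbing flow model
#'
#' Computes `F[i, k]`, the probability that a damped random walk starting at
#' transient node `i` terminates at sink `k`, by solving the sparse system
#' `(I - P_TT) X = P_TK`. Without damping (`mu = 1`) the row sums of `F` are
#' exactly 1 wherever every walk must end in a sink; with damping they fall
#' below 1 by the dissipated probability.
#'
#' @param op An [evolution_operator()] with at least one sink.
#' @return An `itm_flow` result with `F` (transient x sink) and the mean
#'   absorption probability `r_bar` (see [mean_absorption()]).
#' @examples
#' g <- make_fixture("path", 3)
#' res <- solve_absorbing(evolution_operator(g, 0.9, sinks = "c"))
#' res$F # F[a, c] = 0.81/1.19, F[b, c] = 0.9/1.19
#' @export
solve_absorbing <- function(op) {
  stopifnot(inherits(op, "itm_operator"))
  if (length(op$sinks) == 0) {
    abort_validation("The absorbing model requires at least one sink.")
  }
  transient <- transient_nodes(op, "absorbing")
  if (op$mu == 0) {
    warn("mu = 0: all walkers dissipate immediately; returning zero flow.")
    F <- matrix(0, length(transient), length(op$sinks),
                dimnames = list(transient, op$sinks))
    return(new_itm_flow("absorbing", 0, op$sources, op$sinks, op$excluded,
                        op$graph, F = F, r_bar = 0))
  }
  if (op$mu == 1) {
    reach <- reachable_to(op$graph, op$sinks)
    stranded <- setdiff(transient, reach)
    if (length(stranded) > 0) {
      abort(paste0(
        "mu = 1 with transient node(s) unable to reach any sink ",
        "(singular system): ", paste(stranded, collapse = ", ")
      ))
    }
  }
  idxK <- match(op$sinks, op$nodes)
  idxT <- match(transient, op$nodes)
  A <- transient_system(op, transient)
  B <- op$P[idxT, idxK, drop = FALSE]
  X <- solve(A, B)
  F <- dense(X, transient, op$sinks)
  res <- new_itm_flow("absorbing", op$mu, op$sources, op$sinks, op$excluded,
                      op$graph, F = F)
  res$r_bar <- mean_absorption(res, op)
  res
}

#' Solve the emitting flow model
#'
#' Computes `H[s, i]`, the expected number of visits to transient node `i`
#' per walker emitted at source `s`, counting every arrival (revisits
#' included) until the walker dissipates or returns to any source. Obtained
#' from the transposed sparse system `(I - P_TT)' Y = P_ST'`.
#'
#' @param op An [evolution_operator()] with at least one source and `mu < 1`
#'   (without damping the emitting system need not converge).
#' @return An `itm_flow` result with `H` (source x transient) and the mean
#'   path length `t_bar` (see [mean_path_length()]).
#' @examples
#' g <- make_fixture("path", 3)
#' res <- solve_emitting(evolution_operator(g, 0.9, sources = "a"))
#' res$H # H[a, b] = 0.9/0.595, H[a, c] = 0.405/0.595
#' @export
solve_emitting <- function(op) {
  stopifnot(inherits(op, "itm_operator"))
  if (length(op$sources) == 0) {
    abort_validation("The emitting model requires at least one source.")
  }
  if (op$mu >= 1) {
    abort_validation("The emitting model requires mu < 1.")
  }
  transient <- transient_nodes(op, "emitting")
  if (op$mu == 0) {
    warn("mu = 0: all walkers dissipate immediately; returning zero flow.")
    H <- matrix(0, length(op$sources), length(transient),
                dimnames = list(op$sources, transient))
    return(new_itm_flow("emitting", 0, op$sources, op$sinks, op$excluded,
                        op$graph, H = H, t_bar = 1))
  }
  idxS <- match(op$sources, op$nodes)
  idxT <- match(transient, op$nodes)
  A <- transient_system(op, transient)
  B <- t(op$P[idxS, idxT, drop = FALSE])
  Y <- solve(t(A), B)
  H <- dense(t(Y), op$sources, transient)
  res <- new_itm_flow("emitting", op$mu, op$sources, op$sinks, op$excluded,
                      op$graph, H = H)
  res$t_bar <- mean_path_length(res)
  res
}

#' Solve the normalized channel flow model
#'
#' With sources and sinks both on the boundary, the channel model traces the
#' likely routes between them. Per source `s` and transient node `i` it
#' reports the normalized visit count
#' `Phi_hat[s, i] = H[s, i] * sum_k F[i, k] / sum_k' F[s, k']`,
#' the expected visits to `i` by walkers from `s` that reach a sink, with the
#' dissipation loss divided out. The source-row denominator is the one-step
#' extension `F[s, k] = sum_j P[s, j] F[j, k] + P[s, k]`, i.e. the total
#' probability that a walker emitted at `s` ever terminates at a sink.
#' Damping here sets the channel width: as `mu` shrinks, visits concentrate
#' on the shortest source-to-sink path.
#'
#' @param op An [evolution_operator()] with at least one source, at least one
#'   sink and `0 < mu < 1`.
#' @return An `itm_flow` result with `H`, `F`, `Phi_hat` and `t_bar`.
#' @examples
#' g <- make_fixture("path", 3)
#' op <- evolution_operator(g, 0.5, sources = "a", sinks = "c")
#' solve_channel(op)$Phi_hat # 1 at b for any mu in (0, 1)
#' @export
solve_channel <- function(op) {
  stopifnot(inherits(op, "itm_operator"))
  if (length(op$sources) == 0 || length(op$sinks) == 0) {
    abort_validation("The channel model requires at least one source and one sink.")
  }
  if (op$mu <= 0 || op$mu >= 1) {
    abort_validation("The channel model requires mu strictly inside (0, 1).")
  }
  transient <- transient_nodes(op, "channel")
  idxS <- match(op$sources, op$nodes)
  idxK <- match(op$sinks, op$nodes)
  idxT <- match(transient, op$nodes)
  A <- transient_system(op, transient)

  if (length(transient) > 0) {
    F <- dense(solve(A, op$P[idxT, idxK, drop = FALSE]), transient, op$sinks)
    H <- dense(t(solve(t(A), t(op$P[idxS, idxT, drop = FALSE]))),
               op$sources, transient)
  } else {
    F <- matrix(0, 0, length(op$sinks), dimnames = list(NULL, op$sinks))
    H <- matrix(0, length(op$sources), 0, dimnames = list(op$sources, NULL))
  }
  # one-step extension of F to the source rows (walker may also step straight
  # into a sink)
  F_src <- as.matrix(op$P[idxS, idxT, drop = FALSE] %*% F) +
    as.matrix(op$P[idxS, idxK, drop = FALSE])
  dimnames(F_src) <- list(op$sources, op$sinks)
  denom <- rowSums(F_src)
  dead <- denom <= 0
  if (any(dead)) {
    abort(paste0(
      "Source(s) with zero probability of reaching any sink: ",
      paste(op$sources[dead], collapse = ", ")
    ))
  }
  Phi_hat <- sweep(H, 2, rowSums(F), "*") / denom
  res <- new_itm_flow("channel", op$mu, op$sources, op$sinks, op$excluded,
                      op$graph, H = H, F = F, Phi_hat = Phi_hat)
  res$F_sources <- F_src
  res$t_bar <- mean_path_length(res)
  res
}

#' Mean path length before termination
#'
#' One plus the mean, over sources, of the total expected visit count: the
#' average number of steps a walker takes before it terminates. For the
#' channel model the normalized visits are used, so the value is bounded
#' below by the shortest source-to-sink hop count.
#'
#' @param result An `itm_flow` from the emitting or channel model.
#' @return A single number, in steps (>= 1).
#' @export
mean_path_length <- function(result) {
  stopifnot(inherits(result, "itm_flow"))
  V <- switch(result$model,
    emitting = result$H,
    channel = result$Phi_hat,
    abort_validation("mean_path_length() applies to emitting or channel results.")
  )
  if (is.null(V) || ncol(V) == 0) return(1)
  1 + mean(rowSums(V))
}

#' Mean absorption probability
#'
#' Averages the total absorption probability `sum_k F[i, k]` over the
#' transient nodes that have a directed path to at least one sink; nodes that
#' cannot reach a sink are left out of the average (their absorption is
#' structurally zero, not a function of damping).
#'
#' @param result An absorbing `itm_flow`.
#' @param op The operator the result came from (optional; the stored graph is
#'   used when omitted).
#' @return A single probability in `[0, 1]`.
#' @export
mean_absorption <- function(result, op = NULL) {
  stopifnot(inherits(result, "itm_flow"))
  if (result$model != "absorbing" || is.null(result$F)) {
    abort_validation("mean_absorption() applies to absorbing results.")
  }
  graph <- if (!is.null(op)) op$graph else result$graph
  reach <- reachable_to(graph, result$sinks)
  connected <- intersect(rownames(result$F), reach)
  if (length(connected) == 0) {
    abort("No transient node has a directed path to any sink.")
  }
  mean(rowSums(result$F[connected, , drop = FALSE]))
}

#' Interference: per-node minimum of visits over all sources
#'
#' Nodes with a high interference value are substantially visited from every
#' source at once, marking the shared interface between several contexts.
#'
#' @param result An emitting or channel `itm_flow`.
#' @return Named numeric vector over transient nodes.
#' @export
interference <- function(result) {
  stopifnot(inherits(result, "itm_flow"))
  V <- switch(result$model,
    emitting = result$H,
    channel = result$Phi_hat,
    abort_validation("interference() applies to emitting or channel results.")
  )
  apply(V, 2, min)
}

#' Unnormalized channel visits
#'
#' The per-sink channel quantity `Phi[s, i, k] = H[s, i] * F[i, k]`: expected
#' visits to `i` by walkers from `s` that terminate at sink `k`, damping
#' included. Reported in long form as a convenience; the normalized
#' `Phi_hat` is the model's headline output.
#'
#' @param result A channel `itm_flow`.
#' @return A tibble with columns `source`, `node`, `sink`, `phi`.
#' @export
raw_phi <- function(result) {
  stopifnot(inherits(result, "itm_flow"))
  if (result$model != "channel") {
    abort_validation("raw_phi() applies to channel results.")
  }
  grid <- tidyr::expand_grid(
    source = rownames(result$H),
    node = colnames(result$H),
    sink = colnames(result$F)
  )
  grid$phi <- result$H[cbind(grid$source, grid$node)] *
    result$F[cbind(grid$node, grid$sink)]
  grid
}

#' Run a flow model end to end
#'
#' Convenience wrapper: optionally calibrates the damping factor from a
#' dissipation criterion ([resolve_mu()]), builds the evolution operator and
#' dispatches to the model solver.
#'
#' @param graph An `itm_graph`.
#' @param model `"emitting"`, `"absorbing"` or `"channel"`.
#' @param sources,sinks Boundary node ids (model-dependent requirements).
#' @param mu Damping factor in `[0, 1]`; give either `mu` or `criterion`.
#' @param criterion A [dissipation_criterion()] used to calibrate `mu`.
#' @return An `itm_flow` result; inspect with [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' g <- make_fixture("path", 3)
#' res <- itm_flow(g, "absorbing", sinks = "c", mu = 0.9)
#' glance(res)
#' @export
itm_flow <- function(graph, model = c("emitting", "absorbing", "channel"),
                     sources = character(), sinks = character(),
                     mu = NULL, criterion = NULL) {
  model <- rlang::arg_match(model)
  if (is.null(mu) == is.null(criterion)) {
    abort_validation("Give exactly one of `mu` or `criterion`.")
  }
  if (!is.null(criterion)) {
    mu <- resolve_mu(graph, model, sources = sources, sinks = sinks,
                     criterion = criterion)
  }
  op <- evolution_operator(graph, mu, sources = sources, sinks = sinks)
  res <- switch(model,
    emitting = solve_emitting(op),
    absorbing = solve_absorbing(op),
    channel = solve_channel(op)
  )
  res$criterion <- criterion
  res
}

#' @export
print.itm_flow <- function(x, ...) {
  cat(sprintf("<itm_flow> %s model, mu = %g\n", x$model, x$mu))
  if (length(x$sources) > 0) {
    cat("  sources:", paste(x$sources, collapse = ", "), "\n")
  }
  if (length(x$sinks) > 0) {
    cat("  sinks:  ", paste(x$sinks, collapse = ", "), "\n")
  }
  if (!is.null(x$t_bar)) cat(sprintf("  mean path length: %.6g steps\n", x$t_bar))
  if (!is.null(x$r_bar)) cat(sprintf("  mean absorption:  %.6g\n", x$r_bar))
  print(head(tidy(x), 10))
  invisible(x)
}
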