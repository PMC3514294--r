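# Monte Carlo walker ensemble: the independent stochastic check on the
# linear-algebra solvers, and a diagnostic tool in its own right.

#' Simulate an ensemble of damped random walks
#'
#' Direct discrete-time simulation of the walk the flow models describe.
#' Each step is: (1) dissipation trial — the walker leaves the network with
#' probability `1 - mu`; (2) a move to an out-neighbour chosen with
#' probability proportional to edge weight (a walker on a dangling node
#' dies); (3) termination check — arrival at a boundary node ends the walk
#' (sinks absorb; in the emitting and channel models any return to a source
#' terminates), and arrival at an excluded node kills the walk. Visits are
#' counted on every arrival at a transient node, revisits included; the
#' starting node is not counted.
#'
#' @param graph An `itm_graph`.
#' @param model `"emitting"`, `"absorbing"` or `"channel"`.
#' @param mu Damping factor in `[0, 1]`.
#' @param sources,sinks Boundary node ids (per model). Walkers in the
#'   emitting/channel models start at the sources, split equally
#'   (deterministic counts, remainder to the first sources).
#' @param start Start node for the absorbing model (a single transient node).
#' @param n_walkers Ensemble size (>= 1).
#' @param seed RNG seed; a fixed seed gives bit-identical results.
#' @param max_steps Per-walk step cap. Walks still alive at the cap count as
#'   truncated; a truncation rate of 0.1% or more is an error, since the
#'   estimates would be biased.
#' @return An `itm_walks` object: per-node mean visit counts with standard
#'   errors (overall and per source), termination counts per boundary node,
#'   dissipated/truncated counts, and model-specific estimates — `F_hat`
#'   (absorbing: termination fractions) or `phi_hat` (channel: visits
#'   conditioned on sink termination) with standard errors.
#' @examples
#' g <- make_fixture("path", 3)
#' sim <- simulate_walks(g, "absorbing", mu = 0.9, sinks = "c",
#'                       start = "a", n_walkers = 5000, seed = 7)
#' sim$F_hat # near 0.81/1.19
#' @export
simulate_walks <- function(graph, model = c("emitting", "absorbing", "channel"),
                           mu, sources = character(), sinks = character(),
                           start = NULL, n_walkers = 10000L, seed = 1L,
                           max_steps = 10000L) {
  model <- rlang::arg_match(model)
  stopifnot(inherits(graph, "itm_graph"))
  if (n_walkers < 1) abort_validation("`n_walkers` must be >= 1.")
  op <- evolution_operator(graph, mu, sources = sources, sinks = sinks)
  nodes <- graph$nodes
  n <- length(nodes)
  transient <- transient_nodes(op, model)
  boundary <- setdiff(nodes, c(transient, graph$excluded))

  if (model == "absorbing") {
    if (is.null(start) || length(start) != 1 || !start %in% transient) {
      abort_validation("Absorbing simulation needs `start`: one transient node.")
    }
    if (length(sinks) == 0) abort_validation("Absorbing simulation needs sinks.")
    pos0 <- rep(match(start, nodes), n_walkers)
    src_of <- rep(1L, n_walkers)
    src_ids <- start
  } else {
    if (length(sources) == 0) {
      abort_validation("Emitting/channel simulation needs sources.")
    }
    nS <- length(sources)
    base <- n_walkers %/% nS
    counts <- rep(base, nS) + (seq_len(nS) <= n_walkers %% nS)
    src_of <- rep(seq_len(nS), counts)
    pos0 <- match(sources, nodes)[src_of]
    src_ids <- sources
  }

  # per-node out-neighbour tables for weight-proportional moves
  W <- methods::as(methods::as(graph$W, "generalMatrix"), "TsparseMatrix")
  nb <- vector("list", n)
  pw <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer()
  ordv <- order(W@i)
  for (k in ordv) {
    i <- W@i[k] + 1L
    nb[[i]] <- c(nb[[i]], W@j[k] + 1L)
    pw[[i]] <- c(pw[[i]], W@x[k])
  }

  excl_idx <- match(graph$excluded, nodes)
  bound_idx <- match(boundary, nodes)
  is_boundary <- seq_len(n) %in% bound_idx
  is_excluded <- seq_len(n) %in% excl_idx

  visits <- matrix(0L, n_walkers, n)
  pos <- pos0
  active <- rep(TRUE, n_walkers)
  term_node <- rep(NA_integer_, n_walkers) # 0 = dissipated/killed

  withr::local_seed(seed)
  for (step in seq_len(max_steps)) {
    act <- which(active)
    if (length(act) == 0) break
    surv <- runif(length(act)) < mu
    died <- act[!surv]
    term_node[died] <- 0L
    active[died] <- FALSE
    mv <- act[surv]
    if (length(mv) == 0) next
    cur <- pos[mv]
    nxt <- integer(length(mv))
    for (u in unique(cur)) {
      sel <- which(cur == u)
      neigh <- nb[[u]]
      if (length(neigh) == 0) {
        nxt[sel] <- 0L # dangling: the walk dies here
      } else if (length(neigh) == 1) {
        nxt[sel] <- neigh
      } else {
        nxt[sel] <- neigh[sample.int(length(neigh), length(sel),
                                     replace = TRUE, prob = pw[[u]])]
      }
    }
    dead <- nxt == 0L | is_excluded[pmax(nxt, 1L)]
    term_node[mv[dead]] <- 0L
    active[mv[dead]] <- FALSE
    absorbed <- !dead & is_boundary[pmax(nxt, 1L)]
    term_node[mv[absorbed]] <- nxt[absorbed]
    active[mv[absorbed]] <- FALSE
    go <- !dead & !absorbed
    if (any(go)) {
      w_go <- mv[go]
      n_go <- nxt[go]
      idx <- cbind(w_go, n_go)
      visits[idx] <- visits[idx] + 1L
      pos[w_go] <- n_go
    }
  }

  truncated <- sum(active)
  if (truncated / n_walkers >= 0.001) {
    abort(sprintf(
      "Truncation rate %.4f >= 0.1%%: increase max_steps (currently %d).",
      truncated / n_walkers, max_steps
    ))
  }

  col_mean <- colMeans(visits)
  col_var <- (colMeans(visits^2) - col_mean^2) * n_walkers / (n_walkers - 1)
  out <- list(
    model = model, mu = mu, n_walkers = n_walkers, seed = seed,
    max_steps = max_steps, nodes = nodes, transient = transient,
    visits = setNames(col_mean, nodes),
    visits_se = setNames(sqrt(pmax(col_var, 0) / n_walkers), nodes),
    terminations = setNames(
      vapply(seq_len(n), function(i) sum(term_node == i, na.rm = TRUE),
             numeric(1)),
      nodes
    ),
    dissipated = sum(term_node == 0L, na.rm = TRUE),
    truncated = truncated
  )

  if (model %in% c("emitting", "channel")) {
    nS <- length(src_ids)
    Hm <- matrix(0, nS, n, dimnames = list(src_ids, nodes))
    Hse <- Hm
    for (s in seq_len(nS)) {
      rows <- which(src_of == s)
      m <- colMeans(visits[rows, , drop = FALSE])
      v <- (colMeans(visits[rows, , drop = FALSE]^2) - m^2) *
        length(rows) / (length(rows) - 1)
      Hm[s, ] <- m
      Hse[s, ] <- sqrt(pmax(v, 0) / length(rows))
    }
    out$visits_by_source <- Hm
    out$visits_by_source_se <- Hse
  }
  if (model == "absorbing") {
    frac <- out$terminations[sinks] / n_walkers
    out$F_hat <- frac
    out$F_se <- sqrt(frac * (1 - frac) / n_walkers)
  }
  if (model == "channel") {
    sink_idx <- match(sinks, nodes)
    nS <- length(src_ids)
    phi <- matrix(NA_real_, nS, n, dimnames = list(src_ids, nodes))
    phi_se <- phi
    sink_frac <- numeric(nS)
    for (s in seq_len(nS)) {
      rows <- which(src_of == s)
      hit <- rows[term_node[rows] %in% sink_idx]
      sink_frac[s] <- length(hit) / length(rows)
      if (length(hit) > 1) {
        m <- colMeans(visits[hit, , drop = FALSE])
        v <- (colMeans(visits[hit, , drop = FALSE]^2) - m^2) *
          length(hit) / (length(hit) - 1)
        phi[s, ] <- m
        phi_se[s, ] <- sqrt(pmax(v, 0) / length(hit))
      }
    }
    out$phi_hat <- phi
    out$phi_se <- phi_se
    out$sink_fraction <- setNames(sink_frac, src_ids)
  }
  structure(out, class = "itm_walks")
}

#' @export
print.itm_walks <- function(x, ...) {
  cat(sprintf(
    "<itm_walks> %s model, mu = %g, %d walkers (%d dissipated, %d truncated)\n",
    x$model, x$mu, x$n_walkers, x$dissipated, x$truncated
  ))
  invisible(x)
}

#' @describeIn simulate_walks Per-node tibble of ensemble estimates:
#'   mean visit counts with standard errors and termination counts.
#' @param x An `itm_walks` object.
#' @param ... Unused.
#' @method tidy itm_walks
#' @export
tidy.itm_walks <- function(x, ...) {
  tibble(
    node = x$nodes,
    visits = unname(x$visits),
    se = unname(x$visits_se),
    terminations = unname(x$terminations)
  )
}
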