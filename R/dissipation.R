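# Calibrating the damping factor from a target flow statistic.

#' Dissipation criterion
#'
#' The damping factor can be given directly, or indirectly through a model
#' statistic that is easier to reason about:
#' \describe{
#'   \item{`direct_mu`}{`value` is the damping factor itself, in `[0, 1]`.}
#'   \item{`path_deviation_abs`}{emitting/channel: target mean path length
#'     exceeds the shortest source-to-sink hop count by `value` steps. For
#'     the emitting model (no sinks) the baseline is the minimal one-step
#'     walk, i.e. the target is `1 + value`.}
#'   \item{`path_deviation_rel`}{as above but proportional: target is
#'     `L * (1 + value)` with `L` the shortest-path hop count.}
#'   \item{`absorption_prob`}{absorbing only: target mean absorption
#'     probability `r_bar`, in `(0, 1]`.}
#' }
#'
#' @param kind One of the four criterion kinds above.
#' @param value Target value, interpreted per `kind`.
#' @return An object of class `itm_criterion`.
#' @export
dissipation_criterion <- function(kind = c("direct_mu", "path_deviation_abs",
                                           "path_deviation_rel",
                                           "absorption_prob"),
                                  value) {
  kind <- rlang::arg_match(kind)
  if (!is.numeric(value) || length(value) != 1 || is.na(value)) {
    abort_validation("Criterion `value` must be a single number.")
  }
  ok <- switch(kind,
    direct_mu = value >= 0 && value <= 1,
    path_deviation_abs = value >= 0,
    path_deviation_rel = value >= 0,
    absorption_prob = value > 0 && value <= 1
  )
  if (!ok) {
    abort_validation(sprintf("Criterion value %g is out of range for kind '%s'.",
                             value, kind))
  }
  structure(list(kind = kind, value = value), class = "itm_criterion")
}

# the model statistic as a function of mu
flow_statistic <- function(graph, model, sources, sinks) {
  function(mu) {
    op <- evolution_operator(graph, mu, sources = sources, sinks = sinks)
    switch(model,
      emitting = solve_emitting(op)$t_bar,
      channel = solve_channel(op)$t_bar,
      absorbing = solve_absorbing(op)$r_bar
    )
  }
}

#' Calibrate the damping factor from a dissipation criterion
#'
#' Finds `mu` in `(0, 1)` such that the model statistic — mean path length
#' `t_bar` for emitting/channel, mean absorption probability `r_bar` for
#' absorbing — hits the target implied by the criterion. Both statistics
#' increase with `mu`, so a unique root is bracketed on
#' `[1e-6, 1 - 1e-6]` and located by Newton iteration with a central
#' finite-difference derivative, falling back to bisection whenever a Newton
#' step would leave the current bracket. Convergence is declared on the
#' statistic, `|f(mu) - target| < 1e-8 * max(1, target)`, because the target
#' is what the user specified.
#'
#' @inheritParams itm_flow
#' @param criterion A [dissipation_criterion()].
#' @param max_iter Iteration cap (default 100).
#' @return The calibrated damping factor.
#' @examples
#' g <- make_fixture("path", 3)
#' crit <- dissipation_criterion("absorption_prob", 0.718487)
#' resolve_mu(g, "absorbing", sinks = "c", criterion = crit) # ~0.9
#' @export
resolve_mu <- function(graph, model = c("emitting", "absorbing", "channel"),
                       sources = character(), sinks = character(),
                       criterion, max_iter = 100) {
  model <- rlang::arg_match(model)
  if (!inherits(criterion, "itm_criterion")) {
    abort_validation("`criterion` must be created by dissipation_criterion().")
  }
  if (criterion$kind == "direct_mu") return(criterion$value)
  if (criterion$kind == "absorption_prob" && model != "absorbing") {
    abort_validation("absorption_prob criteria apply only to the absorbing model.")
  }
  if (criterion$kind != "absorption_prob" && model == "absorbing") {
    abort_validation("Path-length criteria apply only to emitting/channel models.")
  }

  target <- switch(criterion$kind,
    absorption_prob = criterion$value,
    path_deviation_abs = {
      L <- if (model == "channel") shortest_hops(graph, sources, sinks) else 1
      if (!is.finite(L)) abort_validation("No directed path from any source to any sink.")
      L + criterion$value
    },
    path_deviation_rel = {
      L <- if (model == "channel") shortest_hops(graph, sources, sinks) else 1
      if (!is.finite(L)) abort_validation("No directed path from any source to any sink.")
      L * (1 + criterion$value)
    }
  )

  f <- flow_statistic(graph, model, sources, sinks)
  lo <- 1e-6
  hi <- 1 - 1e-6
  tol <- 1e-8 * max(1, target)
  f_lo <- f(lo)
  f_hi <- f(hi)

  if (abs(f_hi - f_lo) < tol) {
    # statistic does not respond to mu (e.g. single-path channel): any mu
    # reproduces the target if it is attainable at all
    if (abs(f_lo - target) <= max(tol, 1e-6 * max(1, target))) {
      warn(sprintf(
        "Target statistic %g is independent of mu here; returning mu = 0.5.",
        target
      ))
      return((lo + hi) / 2)
    }
    abort(sprintf(
      "Target %g unattainable: statistic is constant at %g on (0, 1).",
      target, f_lo
    ))
  }
  if (target < f_lo - tol || target > f_hi + tol) {
    abort(sprintf(
      "Target %g outside the achievable range [%g, %g] on mu in (0, 1).",
      target, f_lo, f_hi
    ))
  }

  # safeguarded Newton on g(mu) = f(mu) - target, bracket [lo, hi] maintained
  x <- (lo + hi) / 2
  g_x <- f(x) - target
  for (iter in seq_len(max_iter)) {
    if (abs(g_x) < tol) return(x)
    if (g_x > 0) hi <- x else lo <- x
    h <- min(1e-6, (hi - lo) / 4)
    d <- (f(min(x + h, hi)) - f(max(x - h, lo))) /
      (min(x + h, hi) - max(x - h, lo))
    x_new <- if (is.finite(d) && d > 0) x - g_x / d else NA_real_
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi) {
      x_new <- (lo + hi) / 2 # bisection fallback keeps the iterate bracketed
    }
    x <- x_new
    g_x <- f(x) - target
  }
  abort(sprintf(
    "Damping calibration did not converge in %d iterations (target %g).",
    max_iter, target
  ))
}
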