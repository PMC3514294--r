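---
title: "Damped random-walk information flow: models, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Damped random-walk information flow: models, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itmflow)
```

## The walk and its operator

`itmflow` models a network as a weighted directed graph: node set, positive
weights $W_{ij}$ on directed edges. A discrete-time walker at node $i$
first survives a dissipation trial with probability $\mu \in [0,1]$ (the
damping factor) and then moves to $j$ with probability proportional to
$W_{ij}$. Folding damping into the move gives the row-substochastic
evolution operator

$$P_{ij} = \mu\, \frac{W_{ij}}{\sum_{j'} W_{ij'}},$$

so every node with outgoing weight leaks exactly $1-\mu$ of its walkers per
step. Damping is what keeps the retrieved module local: without it, long
walks would wander the whole graph and the most visited nodes would simply
be the global hubs. It also has a physical reading — information carried
through a signaling network degrades in transmission.

Three boundary conditions give the three models. With $T$ the transient
nodes and $G = (I - P_{TT})^{-1}$:

* **Absorbing** (sinks $K$): $F_{ik} = (G\,P_{TK})_{ik}$, the probability a
  walk from $i$ ends at sink $k$. $\sum_k F_{ik} = 1$ exactly when $\mu = 1$
  and every walk must end in a sink; damping makes the sum smaller.
* **Emitting** (sources $S$; return to any source terminates):
  $H_{si} = (P_{ST}\,G)_{si}$, the expected visits to $i$ per walker from
  $s$. Visits count every arrival, so $H$ may exceed 1.
* **Normalized channel** (both boundaries): per source,
  $\hat\Phi_{si} = H_{si} \sum_k F_{ik} \big/ \sum_{k'} F_{sk'}$ — visits
  by walkers that actually reach a sink, with the dissipation loss divided
  out. Here $\mu$ controls the *width* of the source-to-sink channel rather
  than the reach of the flow.

Both linear systems are solved with a sparse LU factorization of
$I - P_{TT}$ (via the Matrix package) against a narrow block of right-hand
sides — one solve per boundary set, one transposed solve for $H$; the dense
fundamental matrix $G$ is never materialized, which is what makes
genome-scale networks feasible.

### Edge semantics

Raw networks arrive as typed multi-edges. Each type is directed,
undirected (the default) or ignored; multi-edges collapse by summing
weights per direction, undirected edges contributing to both directions. A
self-loop contributes its weight once — its forward and backward directions
are the same matrix entry, and doubling it would contradict the
default-weight rule below. Two weighting modes exist: *default* mode (no
usable weight attribute) assigns 2 to self-loops and 1 to every other edge,
and *attribute* mode takes the supplied column, treating missing values as
zero weight (the edge then vanishes). Excluded nodes dissipate all arriving
flow: they keep incoming entries (their neighbours' normalization still
counts the lost probability) but lose all outgoing ones. Deleting them
instead would silently hand their flow back to the surviving neighbours,
which is exactly the artifact exclusion exists to prevent. Node order is
fixed lexicographically (byte order) at construction so that matrices and
output files are byte-reproducible.

### Degenerate inputs and endpoints

$\mu = 0$ returns the all-zero result with a warning (every walker dies
before its first move). $\mu = 1$ is allowed only for the absorbing model
and only when every transient node can reach a sink — otherwise
$I - P_{TT}$ is singular and the offending nodes are named in the error.
Dangling nodes (zero out-weight) are legal: their $P$ row is zero and a
walker arriving there is lost. Sources that are also sinks are rejected;
the channel transient set strictly excludes both boundaries, and the
source-row denominator $\sum_{k'} F_{sk'}$ is obtained by the one-step
extension $F_{sk} = \sum_j P_{sj} F_{jk} + P_{sk}$ — the termination
probability of a walker emitted at $s$, which is the quantity the
normalization calls for. A source with zero denominator (no path to any
sink) is an error naming the source.

## Summary statistics and damping calibration

Users rarely think in units of $\mu$. Two statistics translate:

* mean path length $\bar t = 1 + \operatorname{mean}_s \sum_j H_{sj}$
  (emitting; with $\hat\Phi$ for channel, where $\bar t$ is bounded below
  by the shortest source-to-sink hop count, so targets are expressed as a
  deviation from that bound, absolute in steps or relative);
* mean absorption probability
  $\bar r = \operatorname{mean}_i \sum_k F_{ik}$, averaged only over
  transient nodes with a directed path to at least one sink (for the rest
  the sum is structurally zero and would only dilute the average).

Both are strictly increasing in $\mu$ on $(0,1)$, so a target value has at
most one solution. `resolve_mu()` brackets it on
$[10^{-6},\, 1 - 10^{-6}]$, verifies attainability (reporting the
achievable range otherwise), and runs Newton iteration with a central
finite-difference derivative ($h = 10^{-6}$, clipped to the bracket); any
step leaving the bracket is replaced by bisection, so iterates never escape
$(0,1)$. Each statistic evaluation is one sparse solve; the
finite-difference derivative costs two more, which is cheaper to maintain
than the exact derivative system and accurate enough for a safeguarded
method. Convergence is declared on the statistic,
$|f(\mu) - \text{target}| < 10^{-8}\max(1, \text{target})$, because the
statistic — not $\mu$ — is what the user specified. For the emitting model
the shortest-path baseline is taken as 1 (the minimal one-step walk), so
absolute/relative deviations remain usable there too. When the statistic
does not respond to $\mu$ at all (a single-path channel has $\bar t$ equal
to the path length for every $\mu$), the solver returns the bracket
midpoint 0.5 with a warning instead of failing: any $\mu$ reproduces the
target.

## Ranking, selection, display

A ranking attribute maps each transient node to a nonnegative value:
per-source visits, their total, the *interference* $\min_s H_{si}$ (large
only where every source's flow overlaps), per-sink absorption or its
total, or any custom column carried in from an imported results file. The
significant head of the ranking is chosen by top-$k$, by a strict cutoff,
or by the participation ratio

$$\mathrm{PR}(v) = \operatorname{round}\!\left(\frac{(\sum_i v_i)^2}{\sum_i v_i^2}\right),$$

the standard effective-count statistic: scale-invariant (multiplying all
values by $c>0$ changes nothing), $n$ for uniform values, 1 for a single
spike. Rounding is to nearest rather than floor — the closest integer
count. Display colors mix the subtractive primaries cyan, magenta and
yellow, one per attribute (at most three), each scaled by
$s(v)/s(v_{\max})$ with $s$ linear, square-root (default — flow values
span decades and square-root keeps mid-range structure visible) or
$\log(1+v)$; the blend is $\mathrm{RGB} = (1-c,\, 1-m,\, 1-y)$, so no flow
is white and a node dominated by one source shows that source's hue. A
single attribute may instead be binned into an eight-color sequential
palette (`itm_palette8`, replaceable).

## Files

Results export as self-contained tab-delimited text: `#`-prefixed
`key<TAB>value` headers hold the query (model, $\mu$, criterion, boundary
and excluded sets, $\bar t$/$\bar r$), then one row per node with any
nonzero value under `ITM<model><run>[<tag>]` columns plus `total`,
`interference` and `color`, ordered by descending total with ties broken
by node id. Numbers are written with 17 significant digits, which
round-trips IEEE doubles exactly — re-import reproduces every matrix entry
to well below $10^{-12}$. On import, rows whose node id is not in the
target graph are skipped (count reported), and unknown columns become
custom ranking attributes, supporting the derived-attribute workflow
(e.g. averaging two sources into one column). Exports default to
`run_id = 1` so identical queries yield byte-identical files; the
per-directory sidecar counter (`next_run_id()`) is opt-in for users who
want unique labels across runs.

## The Monte Carlo oracle

`simulate_walks()` is a direct implementation of the walk semantics —
dissipation trial, weight-proportional move, boundary check, in that order,
matching $P = \mu \cdot (\text{row-normalized } W)$ — and shares nothing
with the linear-algebra path except the graph. That independence is the
point: on any fixture the two routes must agree within Monte Carlo error,
and the test suite asserts exactly that (below). Conventions worth
recording: a visit is counted on every arrival at a transient node and
never at the start node; arrival at a source terminates the walk in the
emitting and channel models (including via a source self-loop); arrival at
an excluded node or a dangling node kills the walk; walkers split equally
across multiple sources with deterministic counts. Runs are seeded and
bit-reproducible. A step cap guards unbounded walks; if 0.1% or more of
walks hit the cap the simulator refuses to report (truncation would bias
the visit means) and asks for a larger cap.

## What the fixtures do and do not show

Validation runs on four generated families: the 3-node path (closed-form
solutions), a two-arm parallel-paths graph (unique shortest path), a square
lattice with 10% of nodes and edges removed (irregular planar mesh), and
connected Erdős–Rényi graphs. The headline checks, sized to run in a few
seconds on one CPU:

* conservation: $\sum_k F_{ik} = 1$ at every transient node when $\mu = 1$
  (tolerance $10^{-10}$), on the path and a 20-node random graph;
* oracle agreement: $H$, $F$ and $\hat\Phi$ within four standard errors of
  200,000-walker ensembles on the path, parallel-paths and 20-node random
  fixtures;
* calibration round trips: $\mu^* \in \{0.1, 0.5, 0.9\}$ recovered to
  $10^{-6}$ from $\bar t(\mu^*)$ and $\bar r(\mu^*)$;
* channel limits: $\hat\Phi = 1$ on single-path intermediates for every
  $\mu$; off-shortest-path mass below $10^{-3}$ at $\mu = 0.01$;
  $\bar t \ge$ shortest-path hops;
* lossless export/import on every model and fixture;
* solver residuals $\|(I - P_{TT})x - b\|_\infty < 10^{-9}$.

These fixtures are small, undirected and unit-weighted; they exercise the
algebra, the conventions and the numerics, not the statistical texture of
real interactomes (degree heterogeneity, weight skew, directed regulatory
layers). Passing them shows the engine computes its models correctly, not
that a particular biological conclusion follows — on real data the choice
of weights, boundaries, excluded hubs and damping remains the user's
modelling decision.

## Known limitations

Damping is uniform: per-node dissipation rates are out of scope, as are
stationary/eigenvector analyses and betweenness-style centralities. The
results-file dialect is self-contained but not byte-compatible with any
external tool. The raw per-sink channel quantity
$\Phi_{sik} = H_{si} F_{ik}$ is exposed (`raw_phi()`) as a convenience;
only the normalized $\hat\Phi$ is part of the validated surface.
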