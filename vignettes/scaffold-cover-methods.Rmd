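---
title: "Greedy path-cycle scaffolding: model, feasibility functions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy path-cycle scaffolding: model, feasibility functions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffcover)
```

## The model

A scaffold graph `(G*, M*, ω)` encodes a fragmented assembly: vertices are
contig extremities, the perfect matching `M*` pairs the two extremities of
each contig, and every non-matching ("link") edge carries a non-negative
weight expressing mapping support for the adjacency of two extremities. A
candidate genome with `sigma_p` linear and `sigma_c` circular chromosomes is
a set `S` of link edges, no two sharing a vertex, such that `S + M*` splits
into exactly `sigma_p` alternating paths and `sigma_c` alternating cycles;
path ends are matching edges, and an untouched matching edge is a path of
length one. Two consequences used throughout the package: a valid full
solution has exactly `|M*| - sigma_p` link edges (each path contributes one
link edge fewer than its matching edges, each cycle the same number), and an
alternating cycle needs at least two matching edges, since the graph is
simple.

The optimisation version (maximise total link weight) is NP-hard, so the
package follows the greedy strategy: scan link edges by decreasing weight
and accept an edge whenever (i) both endpoints are free, and (ii) a
*feasibility function* certifies that the enlarged partial solution still
extends to exactly `(sigma_p, sigma_c)`. Feasibility is downward monotone —
removing an edge from a feasible partial solution keeps it feasible — which
is also why the greedy never needs a repair phase: whenever the empty
solution is feasible, the scan necessarily terminates in a complete valid
solution (any missing extension edge would have been accepted when its turn
came).

## Feasibility on complete graphs

On a complete scaffold graph, any two path extremities are adjacent, so only
component statistics matter. Let `c` be the cycles already closed by the
partial solution, `P` its path components (untouched matching edges
included), `M2` those with at least two matching edges, and
`k = sigma_c - c`. The predicate used by `feasible_complete()` is

* `k >= 0`;
* `P >= sigma_p + k` (components never split);
* `P + min(k, M2) >= sigma_p + 2k`;
* `sigma_p + k >= 1` whenever `P > 0`, and `P = 0` forces `sigma_p = k = 0`.

The third line is the subtle one: a cycle is formed either from one path
with two or more matching edges (closing a single path needs a link edge
between its two ends, impossible for a lone matching edge in a simple
graph) or by joining two or more paths. Counting matching edges alone is
not enough — components of sizes `[3, 1, 1]` with one path and two cycles
requested satisfy every counting bound yet are infeasible, because the
single-edge paths cannot close alone and no spare path remains. The
predicate is validated exhaustively against the brute-force oracle on all
complete instances with up to six matching edges (all `(sigma_p, sigma_c)`
pairs, random partial solutions), which is the test we trust over any
closed-form argument.

## Feasibility on connected cluster graphs

A connected cluster graph splits into cliques joined by bridges
(`build_cluster_structure()` verifies the decomposition and roots the clique
tree; by convention only non-matching bridges separate cliques, so a
matching edge that is a cut edge must first be absorbed into a clique by
`complete_to_class()`). The feasibility function is a bottom-up dynamic
program over four nested scopes — vertex with its child subtrees,
alternating element (a component of the partial solution inside one clique),
subclique, clique — whose tables are *entry vectors*: for each cycle count
`i` up to `sigma_c`, the exact set of path counts realisable by a solution
of the current subgraph with `i` cycles. Entry sets are stored as explicit
integer sets, not intervals: printed tables elsewhere suggest eligible sets
are contiguous, but contiguity is an empirical observation we decline to
assume, and the set representation costs nothing at these sizes.

Vectors combine with four operations (`ev_compose()`): juxtaposition (plain
convolution), merger of `t` paths into one (`-(t-1)` paths), closing of `t`
paths into a cycle (`-t` paths, `+1` cycle), and absorption of a path into
an absorbent link edge (`-1` path). Solutions are classified by how the rest
of the graph can still interact with them: closeable (a path with both ends
free), extensible (a free path end), frozen (neither), absorbent (a
replaceable non-forced link edge), plus the two mixed classes needed during
the subclique fold (closeable-with- and closeable-without-extensible). At a
bridge only a single edge can cross, so vertex and clique scopes carry only
frozen/extensible tables.

Bookkeeping convention: extending a child path across a bridge up to a
clique vertex relocates the path's endpoint and leaves the path count
unchanged; when that dangling path later fuses with the element path through
the vertex's matching edge, the two components become one and the count
drops by one at the element scope. Closing an element's path into a cycle
through the clique edge between its extremities requires at least two
matching edges. The per-element fold over a subclique follows the class
transition table; one transition absent from the prose we reconstructed it
from — a merger between an accumulated closeable-only solution and an
extensible element, which lands in the extensible class — is demonstrably
necessary (a two-clique instance with a single matching edge in the root
clique loses its single-path solutions without it) and is included. The
arbiter for every such ambiguity is *set-level oracle equivalence*: on
exhaustive clique-tree shapes (up to three cliques of 2/4/6 vertices, both
door placements) and 500 seeded random cluster instances, with empty and
random partial solutions, the root entry vectors must equal the exact
achievable `(paths, cycles)` profile enumerated by the C++ oracle. That
equivalence is a test, not a calibration: the DP is correct or the suite is
red.

One DP pass computes the eligible path sets for *all* cycle counts at once
(`cluster_eligible_paths()`), so a feasibility query is a set membership and
the equivalence tests compare whole profiles rather than single booleans.

## Exact oracle

`brute_force_feasible()`, `brute_force_optimum()` and
`brute_force_profile()` share one C++ backtracking core: repeatedly take the
smallest unresolved contig extremity and branch over every link edge at it
(merging two components or closing one into a cycle) or declare it a path
end, so each full solution is enumerated exactly once. Structural pruning
(path/cycle budgets; a component with one declared end can only finish as a
path) keeps the reduction instances tractable; in optimum mode an admissible
bound — current weight plus the sum of the largest still-placeable weights —
discards only branches that cannot strictly improve the incumbent, so optima
are exact and, with `prune = FALSE`, solution counts are exhaustive (the
4-cycle instance has exactly four full solutions, which the suite asserts).
Caps (default ten matching edges, explicit override) make the exponential
cost a conscious choice; the acceptance runs use up to 26 matching edges on
the sparse reduction outputs, where pruning bites.

## Generators and their conditions

* `random_instance("cluster")` — a random clique tree: up to three cliques
  with even sizes drawn from {2, 4, 6} (bounded so instances stay within
  oracle reach, 4–8 matching edges in the ratio suites), bridges between
  uniformly chosen parent/child vertices, all link weights uniform integers
  in 0..10, and `(sigma_p, sigma_c)` drawn uniformly from the exactly
  achievable pairs. `random_instance("complete")` matches this protocol on
  complete graphs with a random perfect matching.
* `construction_sparse(G, ell)` — the decision-hardness reduction: a
  bipartite scaffold graph with one matching edge per edge of the subcubic
  input `G` (girth above `ell`) and `ell - deg(v)` fillers per vertex, wired
  into one alternating vertex-cycle of exactly `ell` matching edges per
  vertex; `k` vertex-cycles are simultaneously realisable iff `G` has an
  independent set of size `k`. The cyclic order inside a vertex-cycle is the
  sorted gadget order (any order satisfying the bipartition works).
* `construction_polyapx(G)` — the weighted reduction: a 6-vertex clique per
  edge, a 4-cycle per vertex, long vertex-cycles threading each vertex's
  edge gadgets with total weight one (the weight sits on the last connector
  into the vertex gadget). For an isolated vertex the long cycle degenerates
  to its 4-cycle and the weight-one label moves to that cycle's closing
  chord, keeping "optimum = independence number" true on all graphs.
* `grid_2xk(k, adversarial_weights = TRUE)` — the 2-by-k grid whose
  weighting forces the greedy (lexicographic tie-break picks `x1-x2` first)
  into weight 1 against an optimum of `k - 1`.
* `tightness_instance()` — a fixed four-clique instance on which the
  cluster-greedy attains exactly the worst-case ratio 5. The caption-level
  description (cliques, parameters, weight scheme) leaves the bridge
  placement and the designated optimum open; this witness — bridges `a-g`,
  `a-i`, `i-m`, optimum `{ag, bd, ce, ik, mo}` — was selected by exhaustive
  search over layouts and then frozen, and the 1-versus-5 behaviour is
  verified by computation, which is the property the instance exists to
  certify.

What the synthetic families do not emulate: real scaffold graphs are much
larger, sparse, with heavy-tailed weights estimated from read mappings, and
reach the cluster class only after completion. Passing the suites therefore
certifies the algorithms' contracts (exactness of the oracles, equivalence
of the DP, ratio bounds under the stated protocols), not genome-scale
accuracy or the behaviour of any particular completion of real data.

## Numerical and design choices

* Weights are non-negative rationals held as doubles; ties in the greedy
  scan break lexicographically on the sorted endpoint pair, ascending, which
  the adversarial instances exploit deliberately.
* Edge identity is an unordered pair; duplicate pairs, loops and negative
  weights are rejected at parse time (`read_scaffold_tsv()`).
* Cycles print with their smallest vertex first, then towards its smaller
  neighbour; paths from their smaller extremity — output is diffable.
* The clique-tree root defaults to the clique containing the smallest
  vertex name and is overridable; results are invariant to relabeling
  (asserted by permutation tests).
* Completion fills each bridge-free component into a clique with zero-weight
  links, merges components joined by a matching bridge, and chains
  disconnected components by zero-weight links between their smallest
  vertices; every original solution survives with identical weight, so the
  optimum never decreases.
* Problem sizes in the shipped suites: ratio suites use 200 instances of
  4–8 matching edges with exact optima; DP equivalence uses the exhaustive
  shape family plus 500 random instances; the reduction checks cover all
  subcubic triangle-free graphs on up to six vertices and all graphs on up
  to four vertices, deduplicated up to isomorphism. These sizes were chosen
  so every expected value is certified by exhaustive search.

## Known limitations

* The cluster DP assumes connectivity and no matching bridge between
  cliques; `complete_to_class()` establishes both, but the block-graph
  generalisation (cut vertices instead of bridges) is out of scope.
* The oracle is exponential by design; it refuses, loudly, above its cap.
* `max_independent_set()` delegates to igraph's exact solver — independence
  numbers are certification input here, not a contribution.
* The greedy's approximation guarantees (3 on complete, 5 on cluster
  graphs) are worst-case; the suites routinely observe ratios below 2.
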