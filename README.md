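# scaffcover

Greedy maximum-weight scaffolding of genome assemblies, modelled as an
alternating path/cycle cover of a *scaffold graph*.

## The problem

After contig assembly, a genome is a bag of contiguous sequences whose order
and orientation are unknown. Paired-end mapping information is summarised in
a scaffold graph (G\*, M\*, ω): each contig contributes one **matching edge**
whose endpoints are its two extremities, and each **link edge** uv carries a
non-negative weight ω(uv), the confidence that extremities u and v are
adjacent in the genome. A genome with σp linear and σc circular chromosomes
corresponds to a decomposition of the matching into exactly σp alternating
paths and σc alternating cycles — components whose edges alternate between
M\* and links, path ends lying in M\*. **Scaffolding** asks whether such a
decomposition exists; **max scaffolding** asks for one of maximum total link
weight. Every full solution uses exactly |M\*| − σp link edges.

The optimisation problem is NP-hard, and on sparse graph classes it is hard
even to approximate (the package ships generators for both hardness
reductions from independent set). The tractable route is a greedy scan of
the link edges in decreasing weight order, accepting an edge whenever a
**feasibility function** certifies that the enlarged partial solution still
extends to exactly (σp, σc). `scaffcover` implements

* `feasible_complete()` — a constant-time predicate for complete scaffold
  graphs; the greedy with this guard is a 3-approximation;
* `feasible_cluster()` — a dynamic program over the rooted clique tree of a
  *connected cluster graph* (cliques joined by bridges), running in
  O(|V|·σc²); the greedy with this guard is a 5-approximation, and the
  package constructs the worst-case instance on which the factor 5 is
  attained exactly;
* `complete_to_class()` — zero-weight supergraph completion taking real,
  sparse graphs into either class without losing any solution;
* `brute_force_feasible()` / `brute_force_optimum()` — exhaustive exact
  solvers (C++ backtracking) used as ground truth on small instances;
* generators: `construction_sparse()` and `construction_polyapx()` (the two
  independent-set reductions), `grid_2xk()` (the unbounded-ratio grid),
  `tightness_instance()` (the ratio-5 witness), `random_instance()` (seeded
  random cluster / complete / subcubic triangle-free families).

## Worked example

The tight worst-case instance for the cluster-graph greedy: four cliques
{a..f}, {g,h}, {i,j,k,l}, {m,n,o,p} joined by bridges a–g, a–i, i–m; all
weights zero except the edge `ac` and the five edges of a designated optimal
solution, which weigh one; three linear chromosomes requested.

```r
library(scaffcover)
b <- tightness_instance()
b$graph
#> Scaffold graph: 16 vertices, 8 matching edges (contigs), 23 link edges
#>   link weights: [0, 1]

greedy_scaffold(b$graph, sigma_p = 3, sigma_c = 0, feasibility = "cluster")
#> Greedy scaffold solution: weight 1, 3 path(s), 0 cycle(s)

brute_force_optimum(b$graph, sigma_p = 3, sigma_c = 0, cap = 8)
#> Oracle: optimum weight 5 (35 solution(s) enumerated)
```

The greedy considers the weight-1 edges first and, under the lexicographic
tie-break, starts with `ac`. That single acceptance saturates both bridge
doors at `a`, makes `bd` close a forbidden cycle and strands the remaining
weight-1 edges, so the greedy finishes with weight 1 while the optimum —
three paths `h-g-a-b-d-c-e-f`, `j-i-k-l`, `n-m-o-p` — has weight 5: the
approximation ratio of 5 is tight. On the adversarial 2×k grid the same
experiment shows the ratio k−1 growing without bound:

```r
g <- grid_2xk(4, adversarial_weights = TRUE)$graph
greedy_scaffold(g, 1, 0, feasibility = "oracle")$weight   #> 1
brute_force_optimum(g, sigma_p = 1, sigma_c = 0)$best_weight  #> 3
```

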