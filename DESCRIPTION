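Package: scaffcover
Title: Greedy Path-Cycle Cover of Genome Scaffold Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genome scaffolding problem viewed as an alternating
    path and cycle cover of a scaffold graph: a simple graph with a perfect
    matching (contigs) and confidence weights on the remaining edges. Provides
    a greedy maximum-weight scaffolder guarded by pluggable feasibility
    functions, including a dynamic-programming feasibility oracle for
    connected cluster graphs (cliques joined by bridges) and a constant-time
    predicate for complete graphs; zero-weight supergraph completion into
    these classes; exact brute-force solvers for small instances; and
    deterministic instance generators covering hardness reductions from
    independent set, adversarial grids, and the tight worst-case example for
    the approximation ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
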