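# Deterministic instance generators: hardness constructions, adversarial
# grids, the tight worst-case example, and seeded random families.

# sample k items from a vector, robust to length-one vectors
sample_from <- function(x, k = 1L, replace = FALSE) {
  x[sample.int(length(x), k, replace = replace)]
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# draw (sigma_p, sigma_c) uniformly at random among the pairs this graph
# can realise (checked with the exact oracle; the all-paths pair always works)
sample_feasible_params <- function(g, cap) {
  n <- n_matching(g)
  cand <- expand.grid(sigma_p = 0:n, sigma_c = 0:(n %/% 2L))
  cand <- cand[cand$sigma_p + 2L * cand$sigma_c <= n, , drop = FALSE]
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    if (brute_force_feasible(g, NULL, cand$sigma_p[i], cand$sigma_c[i],
                             cap = cap)) {
      return(list(sigma_p = as.integer(cand$sigma_p[i]),
                  sigma_c = as.integer(cand$sigma_c[i])))
    }
  }
  list(sigma_p = n, sigma_c = 0L)
}

new_bundle <- function(graph, sigma_p, sigma_c, provenance) {
  structure(list(graph = graph, sigma_p = sigma_p, sigma_c = sigma_c,
                 provenance = provenance),
            class = "instance_bundle")
}

#' @export
print.instance_bundle <- function(x, ...) {
  cat("Instance [", x$provenance$generator, "]: ", sep = "")
  print(x$graph)
  cat("  parameters: sigma_p = ", x$sigma_p, ", sigma_c = ", x$sigma_c, "\n",
      sep = "")
  invisible(x)
}

#' Sparse hardness construction (independent set to scaffolding)
#'
#' Encodes a subcubic graph `G` of girth above `ell` as a bipartite scaffold
#' graph whose alternating girth is exactly `ell`: one matching edge per
#' edge of `G`, plus `ell - deg(v)` filler matching edges per vertex `v`,
#' wired into one alternating "vertex-cycle" of exactly `ell` matching edges
#' per vertex. `G` has an independent set of size `k` iff the output can be
#' decomposed into `k` alternating cycles and `|M*| - ell * k` alternating
#' paths (for `ell = 3`; the generalisation raises the girth). All link
#' weights are zero (the reduction targets the decision problem).
#'
#' @param graph an `igraph` object: simple, undirected, maximum degree at
#'   most 3, girth strictly above `ell`.
#' @param ell alternating girth of the output, at least 3.
#' @return An `instance_bundle`; `sigma_p`/`sigma_c` are set to the trivial
#'   all-paths parameters. Use [construction_sparse_params()] for the
#'   parameters encoding an independent-set threshold `k`.
#' @export
construction_sparse <- function(graph, ell = 3L) {
  stopifnot(inherits(graph, "igraph"), ell >= 3L)
  deg <- igraph::degree(graph)
  if (any(deg > 3L)) {
    stop("input graph is not subcubic: vertex '",
         igraph::V(graph)$name[which(deg > 3L)[1L]] %||% which(deg > 3L)[1L],
         "' has degree ", max(deg))
  }
  gi <- igraph::girth(graph)$girth
  if (is.null(gi) || length(gi) == 0L) gi <- Inf
  if (!is.infinite(gi) && gi <= ell) {
    stop("input graph has girth ", gi, " but girth > ", ell, " is required")
  }
  el <- igraph::as_edgelist(graph, names = FALSE)
  nV <- igraph::vcount(graph)
  m <- nrow(el)
  matching <- matrix(character(0), ncol = 2L)
  # edge gadgets: one matching edge per edge of G, u-side / ub-side bipartition
  for (i in seq_len(m)) {
    matching <- rbind(matching, c(sprintf("u%03d", i), sprintf("ub%03d", i)))
  }
  gadget_of_edge <- function(i) c(u = sprintf("u%03d", i),
                                  ub = sprintf("ub%03d", i))
  links <- matrix(character(0), ncol = 2L)
  for (t in seq_len(nV)) {
    inc <- sort(which(el[, 1L] == t | el[, 2L] == t))
    fill <- max(0L, ell - length(inc))
    cyc <- lapply(inc, gadget_of_edge)
    for (j in seq_len(fill)) {
      me <- c(u = sprintf("x%03d_%02d", t, j), ub = sprintf("xb%03d_%02d", t, j))
      matching <- rbind(matching, unname(me))
      cyc <- c(cyc, list(me))
    }
    # alternating vertex-cycle: ub of each gadget to u of the next
    L <- length(cyc)
    for (j in seq_len(L)) {
      nxt <- cyc[[if (j == L) 1L else j + 1L]]
      links <- rbind(links, c(cyc[[j]][["ub"]], nxt[["u"]]))
    }
  }
  g <- scaffold_graph(matching, links, rep(0, nrow(links)))
  new_bundle(g, sigma_p = n_matching(g), sigma_c = 0L,
             provenance = list(generator = "construction_sparse",
                               ell = as.integer(ell),
                               source_vertices = nV, source_edges = m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parameters encoding an independent-set threshold
#'
#' For a bundle from [construction_sparse()], the parameters asking for `k`
#' vertex-cycles: `sigma_c = k`, `sigma_p = |M*| - ell * k`.
#'
#' @param bundle a `construction_sparse` bundle.
#' @param k requested number of alternating cycles.
#' @return List with `sigma_p` and `sigma_c`.
#' @export
construction_sparse_params <- function(bundle, k) {
  ell <- bundle$provenance$ell
  list(sigma_p = n_matching(bundle$graph) - ell * k, sigma_c = as.integer(k))
}

#' Poly-APX hardness construction (weighted S-reduction from independent set)
#'
#' Encodes an arbitrary simple graph `G` as a weighted scaffold graph: a
#' 6-vertex clique with three matching edges per edge of `G`, a 4-cycle with
#' two matching edges per vertex, and one "long vertex-cycle" per vertex
#' threading its edge gadgets, carrying total weight one (all other edges
#' weigh zero). With `sigma_p = 0` and `sigma_c = |V| + |E|`, the maximum
#' achievable weight equals the independence number of `G`. For an isolated
#' vertex the long vertex-cycle degenerates to its 4-cycle, whose closing
#' chord carries the weight-one label so the identity with the independence
#' number holds on all graphs.
#'
#' @param graph an `igraph` object (simple, undirected).
#' @return An `instance_bundle` with `sigma_p = 0`,
#'   `sigma_c = |V(G)| + |E(G)|`; the provenance records, per vertex, the
#'   vertex set of its long vertex-cycle.
#' @export
construction_polyapx <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  el <- igraph::as_edgelist(graph, names = FALSE)
  nV <- igraph::vcount(graph)
  m <- nrow(el)
  matching <- matrix(character(0), ncol = 2L)
  links <- matrix(character(0), ncol = 2L)
  w <- numeric(0)
  add_link <- function(a, b, wt) {
    links <<- rbind(links, c(a, b)); w <<- c(w, wt)
  }
  uu <- function(i, t) sprintf("u%03d_%03d", i, t)
  uub <- function(i, t) sprintf("ub%03d_%03d", i, t)
  # edge gadgets: 6-cliques
  for (i in seq_len(m)) {
    t <- el[i, 1L]; q <- el[i, 2L]
    e6 <- c(uu(i, t), uub(i, t), uu(i, q), uub(i, q),
            sprintf("e%03d", i), sprintf("eb%03d", i))
    matching <- rbind(matching, c(e6[1L], e6[2L]), c(e6[3L], e6[4L]),
                      c(e6[5L], e6[6L]))
    pairs <- t(utils::combn(e6, 2L))
    mk <- edge_keys(as_edge_matrix(rbind(e6[1:2], e6[3:4], e6[5:6]), "m"))
    keep <- !(edge_keys(as_edge_matrix(pairs, "p")) %in% mk)
    for (r in which(keep)) add_link(pairs[r, 1L], pairs[r, 2L], 0)
  }
  # vertex gadgets: 4-cycles plus the long vertex-cycle wiring
  long_cycles <- list()
  for (t in seq_len(nV)) {
    v1 <- sprintf("v%03d_1", t); v1b <- sprintf("vb%03d_1", t)
    v2 <- sprintf("v%03d_2", t); v2b <- sprintf("vb%03d_2", t)
    matching <- rbind(matching, c(v1, v1b), c(v2, v2b))
    add_link(v1b, v2b, 0)
    inc <- sort(which(el[, 1L] == t | el[, 2L] == t))
    if (length(inc) == 0L) {
      # degenerate long vertex-cycle: the 4-cycle itself, weight one
      add_link(v1, v2, 1)
      long_cycles[[t]] <- c(v1, v1b, v2, v2b)
      next
    }
    add_link(v1, v2, 0)
    for (k in seq_len(length(inc) - 1L)) {
      add_link(uub(inc[k], t), uu(inc[k + 1L], t), 0)
    }
    add_link(v1, uu(inc[1L], t), 0)
    add_link(v2, uub(inc[length(inc)], t), 1)
    long_cycles[[t]] <- c(v1, v1b, v2, v2b,
                          as.vector(rbind(uu(inc, t), uub(inc, t))))
  }
  g <- scaffold_graph(matching, links, w)
  new_bundle(g, sigma_p = 0L, sigma_c = nV + m,
             provenance = list(generator = "construction_polyapx",
                               source_vertices = nV, source_edges = m,
                               long_cycles = long_cycles))
}

#' Adversarial 2-by-k grid
#'
#' The 2-by-k grid with the matching between the rows, asking for one
#' alternating path and no cycle. With `adversarial_weights = TRUE` the
#' weighting makes the greedy algorithm (which then picks `x1-x2` first and
#' is forced into the weight-1 solution) lose a factor of `k - 1` against
#' the optimum, demonstrating that no constant ratio holds on grids.
#'
#' @param k number of columns, at least 2.
#' @param adversarial_weights apply the ratio-(k-1) weighting; otherwise all
#'   link weights are 1.
#' @return An `instance_bundle` with `sigma_p = 1`, `sigma_c = 0`.
#' @export
grid_2xk <- function(k, adversarial_weights = FALSE) {
  stopifnot(k >= 2L)
  wdt <- max(2L, nchar(as.character(k)))
  xs <- sprintf(paste0("x%0", wdt, "d"), seq_len(k))
  ys <- sprintf(paste0("y%0", wdt, "d"), seq_len(k))
  matching <- cbind(xs, ys)
  links <- rbind(cbind(xs[-k], xs[-1L]), cbind(ys[-k], ys[-1L]))
  if (adversarial_weights) {
    # forced post-greedy solution S: odd x-rungs and even y-rungs
    ell <- seq_len(k - 1L)
    wx <- ifelse(ell %% 2L == 1L, ifelse(ell == 1L, 1, 0), 1)
    wy <- ifelse(ell %% 2L == 0L, 0, 1)
    weights <- c(wx, wy)
  } else {
    weights <- rep(1, nrow(links))
  }
  g <- scaffold_graph(matching, links, weights)
  new_bundle(g, sigma_p = 1L, sigma_c = 0L,
             provenance = list(generator = "grid_2xk", k = as.integer(k),
                               adversarial = adversarial_weights))
}

#' Tight worst-case instance for the cluster-graph greedy ratio
#'
#' A connected cluster scaffold graph on four cliques,
#' `{a..f}`, `{g,h}`, `{i,j,k,l}` and `{m,n,o,p}` (eight matching edges,
#' bridges a-g, a-i and i-m), asking for three alternating paths and no
#' cycle. All edges weigh zero except `ac` and the five edges of the
#' designated optimal solution `{ag, bd, ce, ik, mo}`, which weigh one. The
#' greedy algorithm considers `ac` first (lexicographic tie-break among the
#' weight-one edges), accepts it, and is then locked out of every other
#' weight-one edge: `ag` and `ce` die with the saturated endpoints, `bd`
#' would close a cycle, and `ik`/`mo` each strand a clique behind the now
#' unusable bridges at `a`, so the greedy solution has weight 1 while the
#' optimum (three paths `h-g-a-b-d-c-e-f`, `j-i-k-l`, `n-m-o-p`) has weight
#' 5 - the approximation ratio of five is attained.
#'
#' @return An `instance_bundle` with `sigma_p = 3`, `sigma_c = 0`; the
#'   provenance records the designated optimal edge set.
#' @export
tightness_instance <- function() {
  matching <- rbind(c("a", "b"), c("c", "d"), c("e", "f"), c("g", "h"),
                    c("i", "j"), c("k", "l"), c("m", "n"), c("o", "p"))
  mk <- edge_keys(as_edge_matrix(matching, "m"))
  cliques <- list(c("a", "b", "c", "d", "e", "f"), c("g", "h"),
                  c("i", "j", "k", "l"), c("m", "n", "o", "p"))
  links <- matrix(character(0), ncol = 2L)
  for (vs in cliques) {
    if (length(vs) < 3L) next
    pairs <- t(utils::combn(vs, 2L))
    keep <- !(edge_keys(as_edge_matrix(pairs, "p")) %in% mk)
    links <- rbind(links, pairs[keep, , drop = FALSE])
  }
  links <- rbind(links, c("a", "g"), c("a", "i"), c("i", "m"))
  s_opt <- rbind(c("a", "g"), c("b", "d"), c("c", "e"), c("i", "k"),
                 c("m", "o"))
  hot <- c(edge_keys(as_edge_matrix(s_opt, "s")),
           edge_keys(as_edge_matrix(rbind(c("a", "c")), "ac")))
  links <- as_edge_matrix(links, "links")
  w <- ifelse(edge_keys(links) %in% hot, 1, 0)
  g <- scaffold_graph(matching, links, w)
  new_bundle(g, sigma_p = 3L, sigma_c = 0L,
             provenance = list(generator = "tightness_instance",
                               optimal_edges = as_edge_matrix(s_opt, "s"),
                               optimal_weight = 5))
}

#' Random instance families
#'
#' Seeded generators for the test families: `"cluster"` builds a random
#' clique tree (even clique sizes, bridges between random vertices of parent
#' and child, all weights integer in 0..10) and draws the target parameters
#' uniformly from the exactly-achievable (paths, cycles) pairs; `"complete"`
#' builds a complete scaffold graph on a random perfect matching;
#' `"subcubic_trianglefree"` rejection-samples a simple graph with maximum
#' degree 3 and no triangle (returned in the provenance as an igraph, for
#' the hardness constructions).
#'
#' @param kind one of `"cluster"`, `"complete"`, `"subcubic_trianglefree"`.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param min_me,max_me bounds on the number of matching edges (cluster and
#'   complete kinds).
#' @param max_cliques maximum number of cliques (cluster kind).
#' @param size_choices candidate clique vertex counts (cluster kind, even).
#' @param n_vertices vertex count (subcubic kind).
#' @param max_weight weights are drawn uniformly from `0:max_weight`.
#' @return An `instance_bundle` (for `"subcubic_trianglefree"`, the `graph`
#'   element of the provenance holds the igraph and the scaffold slots are
#'   `NULL`).
#' @export
random_instance <- function(kind = c("cluster", "complete",
                                     "subcubic_trianglefree"),
                            seed, min_me = 4L, max_me = 8L, max_cliques = 3L,
                            size_choices = c(2L, 4L, 6L), n_vertices = 6L,
                            max_weight = 10L) {
  kind <- match.arg(kind)
  with_local_seed(seed, {
    if (kind == "cluster") {
      repeat {
        nc <- sample.int(max_cliques, 1L)
        sizes <- sample_from(size_choices, nc, replace = TRUE)
        if (sum(sizes) / 2L >= min_me && sum(sizes) / 2L <= max_me) break
      }
      vtot <- 0L
      cliq <- list()
      matching <- matrix(character(0), ncol = 2L)
      links <- matrix(character(0), ncol = 2L)
      w <- numeric(0)
      for (j in seq_len(nc)) {
        vs <- sprintf("v%03d", vtot + seq_len(sizes[j]))
        vtot <- vtot + sizes[j]
        cliq[[j]] <- vs
        matching <- rbind(matching,
                          matrix(vs, ncol = 2L, byrow = TRUE))
        if (length(vs) > 2L) {
          pairs <- t(utils::combn(vs, 2L))
          mk <- edge_keys(as_edge_matrix(
            matrix(vs, ncol = 2L, byrow = TRUE), "m"))
          keep <- !(edge_keys(as_edge_matrix(pairs, "p")) %in% mk)
          links <- rbind(links, pairs[keep, , drop = FALSE])
          w <- c(w, sample(0:max_weight, sum(keep), replace = TRUE))
        }
      }
      for (j in seq_len(nc)[-1L]) {
        parent <- sample.int(j - 1L, 1L)
        door <- sample_from(cliq[[parent]])
        up <- sample_from(cliq[[j]])
        links <- rbind(links, c(door, up))
        w <- c(w, sample_from(0:max_weight))
      }
      g <- scaffold_graph(matching, links, w)
      pick <- sample_feasible_params(g, cap = max_me)
      new_bundle(g, sigma_p = pick$sigma_p, sigma_c = pick$sigma_c,
                 provenance = list(generator = "random_cluster", seed = seed,
                                   n_cliques = nc, sizes = sizes))
    } else if (kind == "complete") {
      n <- sample_from(min_me:max_me)
      vs <- sprintf("v%03d", seq_len(2L * n))
      perm <- sample(vs)
      matching <- matrix(perm, ncol = 2L, byrow = TRUE)
      pairs <- t(utils::combn(vs, 2L))
      mk <- edge_keys(as_edge_matrix(matching, "m"))
      keep <- !(edge_keys(as_edge_matrix(pairs, "p")) %in% mk)
      links <- pairs[keep, , drop = FALSE]
      w <- sample(0:max_weight, nrow(links), replace = TRUE)
      g <- scaffold_graph(matching, links, w)
      pick <- sample_feasible_params(g, cap = max_me)
      new_bundle(g, sigma_p = pick$sigma_p, sigma_c = pick$sigma_c,
                 provenance = list(generator = "random_complete",
                                   seed = seed, n_me = n))
    } else {
      repeat {
        ig <- igraph::sample_gnp(n_vertices, 0.35)
        igraph::V(ig)$name <- sprintf("g%02d", seq_len(n_vertices))
        gi <- igraph::girth(ig)$girth
        if (is.null(gi) || length(gi) == 0L || is.na(gi)) gi <- Inf
        if (max(igraph::degree(ig)) <= 3L && gi > 3L) break
      }
      new_bundle(NULL, sigma_p = NA_integer_, sigma_c = NA_integer_,
                 provenance = list(generator = "random_subcubic_trianglefree",
                                   seed = seed, graph = ig))
    }
  })
}
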