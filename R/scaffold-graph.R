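#' Construct a scaffold graph
#'
#' A scaffold graph models a fragmented genome assembly: every vertex is a
#' contig extremity, every matching edge joins the two extremities of one
#' contig (so the matching is perfect on a valid graph), and every remaining
#' ("link") edge carries a non-negative confidence weight that the two
#' extremities it joins are adjacent in the genome. Solutions of the
#' scaffolding problem are collections of alternating paths and cycles in this
#' graph: components whose edges alternate between matching and link edges,
#' modelling linear and circular chromosomes.
#'
#' The constructor canonicalises the edge lists (unordered pairs, sorted rows)
#' but performs only structural type checks; use [validate_graph()] to obtain
#' a full diagnostic report, which most algorithms require to be clean.
#'
#' @param matching two-column character matrix (or data frame), one row per
#'   matching edge (contig).
#' @param links two-column character matrix (or data frame), one row per link
#'   edge.
#' @param weights numeric vector of non-negative link weights, one per row of
#'   `links`.
#' @param vertices optional character vector of vertex names; defaults to the
#'   names appearing in the edges. Supplying extra names creates isolated
#'   vertices (which fail validation, as the matching cannot cover them).
#' @return An object of class `scaffold_graph` with elements `vertices`,
#'   `matching`, `links` and `weights`.
#' @examples
#' g <- scaffold_graph(matching = rbind(c("a", "b"), c("c", "d")),
#'                     links = rbind(c("b", "c"), c("d", "a")),
#'                     weights = c(2, 1))
#' validate_graph(g)$ok
#' @export
scaffold_graph <- function(matching, links = NULL, weights = NULL,
                           vertices = NULL) {
  matching <- as_edge_matrix(matching, "matching")
  links <- as_edge_matrix(links, "links")
  if (is.null(weights)) weights <- numeric(0)
  weights <- as.numeric(weights)
  if (length(weights) != nrow(links)) {
    stop("`weights` must have one entry per link edge (",
         nrow(links), " needed, ", length(weights), " given)")
  }
  ord <- order(links[, 1L], links[, 2L])
  links <- links[ord, , drop = FALSE]
  weights <- weights[ord]
  matching <- matching[order(matching[, 1L], matching[, 2L]), , drop = FALSE]
  verts <- sort(unique(c(as.vector(matching), as.vector(links),
                         as.character(vertices))))
  structure(list(vertices = verts, matching = matching, links = links,
                 weights = weights),
            class = "scaffold_graph")
}

# normalise an edge specification into a canonical 2-column character matrix
as_edge_matrix <- function(x, what) {
  if (is.null(x)) return(matrix(character(0), ncol = 2L))
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.character(x) && is.null(dim(x))) x <- matrix(x, ncol = 2L, byrow = TRUE)
  if (!is.matrix(x) || ncol(x) != 2L) {
    stop("`", what, "` must be a 2-column matrix of vertex names")
  }
  x <- matrix(as.character(x), ncol = 2L)
  cbind(pmin(x[, 1L], x[, 2L]), pmax(x[, 1L], x[, 2L]))
}

edge_keys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste(m[, 1L], m[, 2L], sep = "\r")
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat("Scaffold graph: ", length(x$vertices), " vertices, ",
      nrow(x$matching), " matching edges (contigs), ",
      nrow(x$links), " link edges\n", sep = "")
  if (nrow(x$links) > 0L) {
    cat("  link weights: [", min(x$weights), ", ", max(x$weights), "]\n",
        sep = "")
  }
  invisible(x)
}

#' Number of matching edges (contigs) of a scaffold graph
#' @param g a `scaffold_graph`.
#' @return Integer count of matching edges.
#' @export
n_matching <- function(g) nrow(g$matching)

#' Validate a scaffold graph
#'
#' Checks the defining invariants: the graph is simple and loopless, matching
#' and link edges are disjoint, the matching is perfect (every vertex lies in
#' exactly one matching edge), and all link weights are non-negative and
#' finite. Violations are reported as diagnostics, not errors, so that broken
#' inputs can be inspected.
#'
#' @param g a `scaffold_graph`.
#' @return A list with `ok` (logical) and `violations` (character vector, one
#'   message per problem, naming the offending vertex or edge).
#' @export
validate_graph <- function(g) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)
  all_edges <- rbind(g$matching, g$links)
  loops <- all_edges[, 1L] == all_edges[, 2L]
  for (i in which(loops)) {
    note(paste0("loop at vertex '", all_edges[i, 1L], "'"))
  }
  keys <- edge_keys(all_edges)
  dup <- unique(keys[duplicated(keys)])
  for (k in dup) {
    uv <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    note(paste0("duplicate edge {", uv[1L], ", ", uv[2L],
                "} (graph must be simple; matching and link sets disjoint)"))
  }
  if (length(g$vertices) %% 2L == 1L) {
    note("odd number of vertices: no perfect matching possible")
  }
  deg_m <- table(factor(as.vector(g$matching), levels = g$vertices))
  for (vn in g$vertices[deg_m == 0L]) {
    note(paste0("vertex '", vn, "' is not covered by the matching"))
  }
  for (vn in g$vertices[deg_m > 1L]) {
    note(paste0("vertex '", vn, "' lies in ", deg_m[vn],
                " matching edges (matching not a matching)"))
  }
  bad_w <- !is.finite(g$weights) | g$weights < 0
  for (i in which(bad_w)) {
    note(paste0("link edge {", g$links[i, 1L], ", ", g$links[i, 2L],
                "} has invalid weight ", g$weights[i],
                " (weights must be finite and non-negative)"))
  }
  list(ok = length(v) == 0L, violations = v)
}

assert_valid_graph <- function(g) {
  if (!inherits(g, "scaffold_graph")) stop("not a scaffold_graph")
  rep <- validate_graph(g)
  if (!rep$ok) {
    stop("invalid scaffold graph: ", paste(rep$violations, collapse = "; "))
  }
  invisible(g)
}

# canonicalise a partial solution (set of link edges) against g; returns the
# canonical 2-column matrix plus the row indices into g$links
as_solution_edges <- function(g, s) {
  s <- as_edge_matrix(s, "solution")
  if (nrow(s) == 0L) {
    return(list(edges = s, index = integer(0)))
  }
  keys <- edge_keys(s)
  if (anyDuplicated(keys)) stop("solution lists a link edge twice")
  idx <- match(keys, edge_keys(g$links))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("solution edge {", s[bad, 1L], ", ", s[bad, 2L],
         "} is not a link edge of the graph")
  }
  ord <- order(idx)
  list(edges = s[ord, , drop = FALSE], index = idx[ord])
}

matching_partner <- function(g) {
  p <- c(g$matching[, 2L], g$matching[, 1L])
  names(p) <- c(g$matching[, 1L], g$matching[, 2L])
  p
}

#' Decompose a partial solution into alternating paths and cycles
#'
#' The union of a partial solution `s` (a set of link edges, no two sharing a
#' vertex) with the perfect matching is a disjoint union of alternating paths
#' and alternating cycles. This function lists those components in canonical
#' form: paths are oriented from their lexicographically smaller extremity;
#' cycles start at their lexicographically smallest vertex, moving towards its
#' smaller neighbour. A single untouched matching edge counts as an
#' alternating path of length one.
#'
#' @param g a valid `scaffold_graph`.
#' @param s partial solution: 2-column matrix of link edges (or a flat
#'   character vector taken row-wise). May be `NULL` for the empty solution.
#' @param cover_all if `TRUE` (default), matching edges not touched by `s` are
#'   emitted as length-one paths, so the decomposition covers the whole
#'   matching; if `FALSE`, only components containing an `s` edge are listed.
#' @return A list of class `solution_decomposition`: `paths` and `cycles`
#'   (lists of vertex sequences), `sigma_p`, `sigma_c`, `weight` (sum of link
#'   weights used) and `edges` (the canonical solution matrix).
#' @export
decompose_solution <- function(g, s = NULL, cover_all = TRUE) {
  assert_valid_graph(g)
  sol <- as_solution_edges(g, s)
  se <- sol$edges
  sdeg <- table(factor(as.vector(se), levels = g$vertices))
  if (any(sdeg > 1L)) {
    v <- g$vertices[which(sdeg > 1L)[1L]]
    stop("vertex '", v, "' is incident to two solution edges")
  }
  partner <- matching_partner(g)
  spartner <- rep(NA_character_, length(g$vertices))
  names(spartner) <- g$vertices
  spartner[se[, 1L]] <- se[, 2L]
  spartner[se[, 2L]] <- se[, 1L]

  visited <- logical(length(g$vertices))
  names(visited) <- g$vertices
  paths <- list()
  cycles <- list()
  # walk each component of s + matching; endpoints are vertices with no s edge
  for (v0 in g$vertices) {
    if (visited[v0]) next
    if (!is.na(spartner[v0])) next  # start walks at free vertices first
    seq <- character(0)
    v <- v0
    repeat {
      seq <- c(seq, v, partner[v])
      visited[c(v, partner[v])] <- TRUE
      nxt <- spartner[partner[v]]
      if (is.na(nxt)) break
      v <- nxt
    }
    if (!cover_all && length(seq) == 2L) next
    if (seq[1L] > seq[length(seq)]) seq <- rev(seq)
    paths <- c(paths, list(unname(seq)))
  }
  for (v0 in g$vertices) {  # remaining components are cycles
    if (visited[v0]) next
    seq <- character(0)
    v <- v0
    repeat {
      seq <- c(seq, v, partner[v])
      visited[c(v, partner[v])] <- TRUE
      v <- spartner[partner[v]]
      if (v == v0) break
    }
    cycles <- c(cycles, list(canonical_cycle(unname(seq))))
  }
  paths <- paths[order(vapply(paths, `[`, character(1), 1L))]
  cycles <- cycles[order(vapply(cycles, `[`, character(1), 1L))]
  structure(list(paths = paths, cycles = cycles,
                 sigma_p = length(paths), sigma_c = length(cycles),
                 weight = sum(g$weights[sol$index]),
                 edges = se),
            class = "solution_decomposition")
}

canonical_cycle <- function(seq) {
  k <- which(seq == min(seq))[1L]
  n <- length(seq)
  rot <- seq[((seq_len(n) + k - 2L) %% n) + 1L]
  # two traversal directions; pick the one with the smaller second vertex
  alt <- c(rot[1L], rev(rot[-1L]))
  if (alt[2L] < rot[2L]) alt else rot
}

#' @export
print.solution_decomposition <- function(x, ...) {
  cat("Alternating decomposition: ", x$sigma_p, " path(s), ", x$sigma_c,
      " cycle(s), weight ", x$weight, "\n", sep = "")
  for (p in x$paths) cat("  P ", paste(p, collapse = " "), "\n", sep = "")
  for (cc in x$cycles) cat("  C ", paste(cc, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Does a partial solution realise exactly the requested structure?
#'
#' @param g a valid `scaffold_graph`.
#' @param s partial solution (see [decompose_solution()]).
#' @param sigma_p,sigma_c requested numbers of alternating paths (linear
#'   chromosomes) and alternating cycles (circular chromosomes).
#' @return `TRUE` iff the full decomposition of `s` (untouched matching edges
#'   counted as length-one paths) has exactly `sigma_p` paths and `sigma_c`
#'   cycles.
#' @export
solution_is_valid <- function(g, s, sigma_p, sigma_c) {
  d <- decompose_solution(g, s, cover_all = TRUE)
  d$sigma_p == sigma_p && d$sigma_c == sigma_c
}

#' Alternating girth of a scaffold graph
#'
#' The alternating girth is the number of matching edges in the smallest
#' alternating cycle, or `Inf` when the graph has no alternating cycle.
#' Computed by exhaustive depth-first enumeration of alternating cycles with
#' branch-and-bound on the best length found, so it is intended for the small
#' graphs this package manipulates.
#'
#' @param g a valid `scaffold_graph`.
#' @param cap refuse graphs with more matching edges than this (the search is
#'   exponential in the worst case).
#' @return A numeric scalar: the minimum matching-edge count over alternating
#'   cycles, or `Inf`.
#' @export
alternating_girth <- function(g, cap = 24L) {
  assert_valid_graph(g)
  n <- n_matching(g)
  if (n > cap) {
    stop("alternating_girth: graph has ", n, " matching edges, above the cap ",
         cap, " (raise `cap` explicitly to force the exponential search)")
  }
  if (n < 2L || nrow(g$links) < 2L) return(Inf)
  partner <- matching_partner(g)
  edge_of <- match_me_of(g)
  adj <- link_adjacency(g)
  best <- Inf
  for (root in seq_len(n)) {
    a <- g$matching[root, 1L]; b <- g$matching[root, 2L]
    # orient the root edge once (entry a, exit b): each cycle found once
    used <- logical(n); used[root] <- TRUE
    best <- girth_dfs(b, a, root, used, 1L, best, partner, edge_of, adj)
  }
  best
}

girth_dfs <- function(exit, home, root, used, count, best,
                      partner, edge_of, adj) {
  if (count + 1L > best) return(best)  # any extension uses >= count+1 edges
  for (u in adj[[exit]]) {
    if (u == home && count >= 2L) best <- min(best, count)
    me <- edge_of[u]
    if (me <= root || used[me]) next
    used[me] <- TRUE
    best <- girth_dfs(partner[u], home, root, used, count + 1L, best,
                      partner, edge_of, adj)
    used[me] <- FALSE
  }
  best
}

match_me_of <- function(g) {
  e <- rep(seq_len(nrow(g$matching)), 2L)
  names(e) <- c(g$matching[, 1L], g$matching[, 2L])
  e
}

link_adjacency <- function(g) {
  adj <- lapply(g$vertices, function(v) character(0))
  names(adj) <- g$vertices
  for (i in seq_len(nrow(g$links))) {
    u <- g$links[i, 1L]; v <- g$links[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  lapply(adj, sort)
}
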