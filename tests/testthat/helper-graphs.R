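# shared fixtures, all built in code

# minimal scaffold graphs
k2_graph <- function() scaffold_graph(rbind(c("a", "b")))

four_cycle_graph <- function(w = c(1, 1)) {
  scaffold_graph(rbind(c("a", "b"), c("c", "d")),
                 rbind(c("b", "c"), c("a", "d")), w)
}

# igraph on n named vertices from a flat edge vector
mk_igraph <- function(n, edges = integer(0)) {
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) ig <- igraph::add_edges(ig, edges)
  igraph::V(ig)$name <- paste0("w", seq_len(n))
  ig
}

# all simple graphs on exactly n labeled vertices, optionally filtered, then
# deduplicated up to isomorphism
enumerate_graphs <- function(n, filter = NULL) {
  if (n < 2L) return(list(mk_igraph(n)))
  pairs <- t(combn(n, 2))
  np <- nrow(pairs)
  out <- list()
  seen <- character(0)
  for (mask in 0:(2^np - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    adj <- matrix(0L, n, n)
    if (length(sel)) {
      adj[pairs[sel, , drop = FALSE]] <- 1L
      adj <- adj + t(adj)
    }
    if (!is.null(filter) && !filter(adj)) next
    ig <- mk_igraph(n, as.vector(t(pairs[sel, , drop = FALSE])))
    cp <- igraph::canonical_permutation(ig)$labeling
    key <- paste(sort(apply(igraph::as_edgelist(igraph::permute(ig, cp)),
                            1, paste, collapse = "-")), collapse = ",")
    key <- paste(n, key)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- ig
  }
  out
}

subcubic_trianglefree_filter <- function(adj) {
  if (any(rowSums(adj) > 3L)) return(FALSE)
  sum(diag(adj %*% adj %*% adj)) == 0L
}

# a random vertex-disjoint set of link edges, as a partial solution fixture
random_partial_solution <- function(g, target = NULL) {
  if (nrow(g$links) == 0L) return(NULL)
  if (is.null(target)) target <- sample(0:n_matching(g), 1)
  perm <- sample(nrow(g$links))
  used <- character(0)
  sel <- integer(0)
  for (i in perm) {
    if (length(sel) >= target) break
    uv <- g$links[i, ]
    if (!any(uv %in% used)) {
      sel <- c(sel, i)
      used <- c(used, uv)
    }
  }
  g$links[sel, , drop = FALSE]
}

# independent ground truth for the achievable-(paths, cycles) profile:
# enumerate every vertex-disjoint link subset in R and decompose it
slow_profile <- function(g) {
  n <- n_matching(g)
  m <- nrow(g$links)
  counts <- matrix(0L, n + 1L, n %/% 2L + 1L,
                   dimnames = list(paths = 0:n, cycles = 0:(n %/% 2L)))
  for (mask in 0:(2^m - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    s <- g$links[idx, , drop = FALSE]
    if (nrow(s) && anyDuplicated(as.vector(s))) next
    d <- decompose_solution(g, s)
    counts[d$sigma_p + 1L, d$sigma_c + 1L] <-
      counts[d$sigma_p + 1L, d$sigma_c + 1L] + 1L
  }
  counts
}

expect_profile_equiv <- function(g, s = NULL) {
  prof <- brute_force_profile(g, s, cap = n_matching(g))
  el <- cluster_eligible_paths(g, s)
  for (ci in 0:(n_matching(g) %/% 2L)) {
    oracle_set <- as.integer(which(prof[, ci + 1L] > 0) - 1L)
    expect_identical(sort(oracle_set), sort(as.integer(el[[ci + 1L]])),
                     label = paste0("eligible path sets at ", ci, " cycles"))
  }
  invisible(TRUE)
}
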