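# Connected cluster graphs: cliques joined by bridges, rooted as a tree.

as_igraph <- function(g) {
  edges <- rbind(g$matching, g$links)
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L],
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$vertices, stringsAsFactors = FALSE))
}

is_connected_scaffold <- function(g) {
  igraph::is_connected(as_igraph(g))
}

#' Bridges of a scaffold graph
#'
#' A bridge is an edge whose deletion increases the number of connected
#' components. Computed with igraph's linear-time algorithm.
#'
#' @param g a valid, connected `scaffold_graph`.
#' @return Canonical 2-column character matrix of bridge edges (matching or
#'   link), ordered lexicographically.
#' @export
find_bridges <- function(g) {
  assert_valid_graph(g)
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) {
    stop("find_bridges: graph is disconnected")
  }
  eids <- igraph::bridges(ig)
  if (length(eids) == 0L) return(matrix(character(0), ncol = 2L))
  m <- igraph::as_edgelist(ig)[as.integer(eids), , drop = FALSE]
  m <- as_edge_matrix(m, "bridges")
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Recognise and root a connected cluster graph
#'
#' A connected cluster graph admits an edge partition E = E' + B where E'
#' induces a disjoint union of cliques and every edge of B is a bridge.
#' Matching edges are kept inside cliques whenever possible: only
#' non-matching bridges separate cliques, and a matching bridge whose
#' endpoints form components larger than the edge itself is an error (the
#' graph must first be completed, see [complete_to_class()]). Contracting
#' cliques yields a tree, rooted by default at the clique containing the
#' lexicographically smallest vertex; each non-root clique has a unique upper
#' door (its vertex on the bridge towards the parent) and each door knows the
#' child cliques hanging below it.
#'
#' @param g a valid, connected `scaffold_graph`.
#' @param root optional vertex name; the clique containing it becomes the
#'   root.
#' @return An object of class `cluster_structure` with `cliques` (named list
#'   of vertex sets), `clique_of` (vertex to clique id), `bridges`, `root`,
#'   `parent`, `children`, `upper_door`, `parent_door` and `door_children`.
#' @export
build_cluster_structure <- function(g, root = NULL) {
  assert_valid_graph(g)
  ig <- as_igraph(g)
  if (!igraph::is_connected(ig)) {
    stop("build_cluster_structure: graph is disconnected")
  }
  br <- find_bridges(g)
  mk <- edge_keys(g$matching)
  bk <- edge_keys(br)
  link_bridges <- br[!(bk %in% mk), , drop = FALSE]

  ig2 <- igraph::delete_edges(
    ig, igraph::get_edge_ids(ig, as.vector(t(link_bridges))))
  comp <- igraph::components(ig2)$membership
  blocks <- split(names(comp), comp)
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(vapply(blocks, `[`, character(1), 1L))]
  names(blocks) <- paste0("c", seq_along(blocks))
  clique_of <- rep(names(blocks), lengths(blocks))
  names(clique_of) <- unlist(blocks)

  # every block must induce a clique via the non-bridge edges
  have <- c(edge_keys(g$matching), edge_keys(g$links))
  for (cid in names(blocks)) {
    vs <- blocks[[cid]]
    if (length(vs) < 2L) next
    pairs <- t(utils::combn(vs, 2L))
    miss <- which(!(edge_keys(pairs) %in% have))
    if (length(miss)) {
      u <- pairs[miss[1L], 1L]; v <- pairs[miss[1L], 2L]
      stop("not a connected cluster graph: vertices '", u, "' and '", v,
           "' share a block of the bridge decomposition but are not ",
           "adjacent; complete the graph first (see complete_to_class)")
    }
  }

  # clique tree from the link bridges
  root_vertex <- if (is.null(root)) g$vertices[1L] else as.character(root)
  if (!root_vertex %in% g$vertices) {
    stop("root vertex '", root_vertex, "' is not in the graph")
  }
  root_cid <- clique_of[[root_vertex]]
  nb <- lapply(stats::setNames(vector("list", length(blocks)), names(blocks)),
               identity)
  for (i in seq_len(nrow(link_bridges))) {
    u <- link_bridges[i, 1L]; v <- link_bridges[i, 2L]
    cu <- clique_of[[u]]; cv <- clique_of[[v]]
    nb[[cu]] <- rbind(nb[[cu]], c(cv, u, v))  # (other clique, my end, its end)
    nb[[cv]] <- rbind(nb[[cv]], c(cu, v, u))
  }
  parent <- stats::setNames(rep(NA_character_, length(blocks)), names(blocks))
  upper_door <- parent
  parent_door <- parent
  children <- stats::setNames(vector("list", length(blocks)), names(blocks))
  queue <- root_cid
  seen <- stats::setNames(logical(length(blocks)), names(blocks))
  seen[root_cid] <- TRUE
  while (length(queue)) {
    cid <- queue[1L]; queue <- queue[-1L]
    e <- nb[[cid]]
    if (is.null(e)) next
    for (i in seq_len(nrow(e))) {
      other <- e[i, 1L]
      if (seen[other]) next
      seen[other] <- TRUE
      parent[other] <- cid
      parent_door[other] <- e[i, 2L]  # vertex in cid
      upper_door[other] <- e[i, 3L]   # vertex in child
      children[[cid]] <- c(children[[cid]], other)
      queue <- c(queue, other)
    }
  }
  door_children <- list()
  for (cid in names(blocks)) {
    if (is.na(parent[cid])) next
    d <- parent_door[[cid]]
    door_children[[d]] <- sort(c(door_children[[d]], cid))
  }
  structure(list(graph = g, cliques = blocks, clique_of = clique_of,
                 bridges = link_bridges, root = root_cid, parent = parent,
                 children = children, upper_door = upper_door,
                 parent_door = parent_door, door_children = door_children),
            class = "cluster_structure")
}

#' @export
print.cluster_structure <- function(x, ...) {
  cat("Connected cluster graph: ", length(x$cliques), " clique(s), ",
      nrow(x$bridges), " bridge(s), root ", x$root, "\n", sep = "")
  for (cid in names(x$cliques)) {
    cat("  ", cid, " {", paste(x$cliques[[cid]], collapse = ", "), "}",
        sep = "")
    if (!is.na(x$parent[cid])) {
      cat("  parent ", x$parent[cid], " via bridge ",
          x$parent_door[cid], "-", x$upper_door[cid], sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

# components of (s restricted to clique) + (matching restricted to clique):
# the alternating elements of the clique
clique_elements <- function(cs, cid, s_edges) {
  g <- cs$graph
  vs <- cs$cliques[[cid]]
  partner <- matching_partner(g)
  inside <- s_edges[, 1L] %in% vs & s_edges[, 2L] %in% vs
  se <- s_edges[inside, , drop = FALSE]
  spartner <- stats::setNames(rep(NA_character_, length(vs)), vs)
  if (nrow(se)) {
    spartner[se[, 1L]] <- se[, 2L]
    spartner[se[, 2L]] <- se[, 1L]
  }
  visited <- stats::setNames(logical(length(vs)), vs)
  elements <- list()
  for (v0 in vs) {
    if (visited[v0] || !is.na(spartner[v0])) next
    seq <- character(0); v <- v0
    repeat {
      seq <- c(seq, v, partner[[v]])
      visited[c(v, partner[[v]])] <- TRUE
      nxt <- spartner[[partner[[v]]]]
      if (is.na(nxt)) break
      v <- nxt
    }
    if (seq[1L] > seq[length(seq)]) seq <- rev(seq)
    elements <- c(elements, list(list(
      type = "path", vertices = unname(seq),
      extremities = c(seq[1L], seq[length(seq)]),
      inner = if (length(seq) > 2L) seq[-c(1L, length(seq))] else character(0),
      n_me = length(seq) / 2L)))
  }
  for (v0 in vs) {
    if (visited[v0]) next
    seq <- character(0); v <- v0
    repeat {
      seq <- c(seq, v, partner[[v]])
      visited[c(v, partner[[v]])] <- TRUE
      v <- spartner[[partner[[v]]]]
      if (v == v0) break
    }
    elements <- c(elements, list(list(
      type = "cycle", vertices = canonical_cycle(seq),
      extremities = character(0), inner = canonical_cycle(seq),
      n_me = length(seq) / 2L)))
  }
  elements[order(vapply(elements, function(e) e$vertices[1L], character(1)))]
}

#' Alternating elements and subclique of a clique
#'
#' Restricting a partial solution to one clique splits it into alternating
#' elements: paths (possibly single matching edges) and cycles lying inside
#' the clique. For a non-root clique, the subclique is the clique minus the
#' vertices of the element containing its upper door.
#'
#' @param cs a `cluster_structure`.
#' @param clique clique identifier (e.g. `"c1"`).
#' @param s partial solution over the whole graph.
#' @return List with `elements` (each a list with `type`, `vertices`,
#'   `extremities`, `inner`, `n_me`), `door_element` (index of the element
#'   containing the upper door, or `NA` for the root) and `subclique`
#'   (vertex set of the subclique, or `NULL` for the root).
#' @export
alternating_elements_of <- function(cs, clique, s = NULL) {
  stopifnot(inherits(cs, "cluster_structure"))
  if (!clique %in% names(cs$cliques)) stop("unknown clique '", clique, "'")
  se <- as_solution_edges(cs$graph, s)$edges
  els <- clique_elements(cs, clique, se)
  d <- cs$upper_door[[clique]]
  if (is.na(d)) {
    return(list(elements = els, door_element = NA_integer_, subclique = NULL))
  }
  di <- which(vapply(els, function(e) d %in% e$vertices, logical(1)))
  sub <- sort(setdiff(cs$cliques[[clique]], els[[di]]$vertices))
  list(elements = els, door_element = di, subclique = sub)
}

#' Complete a scaffold graph into a graph class by adding zero-weight edges
#'
#' Real scaffold graphs are sparse; the feasibility functions require a
#' complete graph or a connected cluster graph. Completion adds link edges of
#' weight zero, so every solution of the input is a solution of the output
#' with the same weight, and the optimal weight can only grow. Disconnected
#' inputs are first connected by a chain of zero-weight links between the
#' lexicographically smallest vertices of their components. For
#' `target = "cluster"`, each component of the graph minus its bridges is
#' filled into a clique, and components joined by a matching bridge are
#' merged into a single clique so that no matching edge separates cliques.
#'
#' @param g a valid `scaffold_graph`.
#' @param target `"complete"` or `"cluster"`.
#' @return A `scaffold_graph` supergraph of `g` in the requested class.
#' @export
complete_to_class <- function(g, target = c("cluster", "complete")) {
  target <- match.arg(target)
  assert_valid_graph(g)
  have <- c(edge_keys(g$matching), edge_keys(g$links))
  new_edges <- matrix(character(0), ncol = 2L)
  add_missing <- function(vs) {
    if (length(vs) < 2L) return(invisible(NULL))
    pairs <- as_edge_matrix(t(utils::combn(sort(vs), 2L)), "completion")
    miss <- !(edge_keys(pairs) %in% c(have, edge_keys(new_edges)))
    new_edges <<- rbind(new_edges, pairs[miss, , drop = FALSE])
  }
  # connect components first
  ig <- as_igraph(g)
  comp <- igraph::components(ig)$membership
  if (max(comp) > 1L) {
    reps <- vapply(split(names(comp), comp), min, character(1))
    reps <- sort(reps)
    chain <- cbind(reps[-length(reps)], reps[-1L])
    new_edges <- rbind(new_edges, as_edge_matrix(chain, "chain"))
  }
  if (target == "complete") {
    add_missing(g$vertices)
  } else {
    g1 <- if (nrow(new_edges)) {
      scaffold_graph(g$matching, rbind(g$links, new_edges),
                     c(g$weights, rep(0, nrow(new_edges))))
    } else g
    br <- find_bridges(g1)
    mk <- edge_keys(g$matching)
    link_bridges <- br[!(edge_keys(br) %in% mk), , drop = FALSE]
    ig1 <- as_igraph(g1)
    ig2 <- igraph::delete_edges(
      ig1, igraph::get_edge_ids(ig1, as.vector(t(link_bridges))))
    memb <- igraph::components(ig2)$membership
    # merge blocks joined by a matching bridge, so no matching edge is left
    # separating two cliques
    matching_bridges <- br[edge_keys(br) %in% mk, , drop = FALSE]
    for (i in seq_len(nrow(matching_bridges))) {
      a <- memb[[matching_bridges[i, 1L]]]
      b <- memb[[matching_bridges[i, 2L]]]
      memb[memb == b] <- a
    }
    for (vs in split(names(memb), memb)) add_missing(vs)
  }
  if (nrow(new_edges) == 0L) return(g)
  scaffold_graph(g$matching, rbind(g$links, new_edges),
                 c(g$weights, rep(0, nrow(new_edges))))
}
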