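# Feasibility functions: can a partial solution still be extended into
# exactly sigma_p alternating paths and sigma_c alternating cycles?
#
# Two polynomial deciders are provided: a constant-time predicate for
# complete scaffold graphs and a bottom-up dynamic program over the rooted
# clique tree of a connected cluster graph. The DP manipulates "entry
# vectors": for each cycle count i, the set of path counts realisable by
# some solution of the current subgraph with exactly i cycles. Solutions of
# sibling subgraphs are combined with four operations - juxtaposition,
# merger (t paths joined into one, path count drops by t-1), closing (t
# paths closed into one cycle: path count drops by t, cycle count rises by
# one) and absorption (a path replaces a non-matching edge of another, path
# count drops by one).

ev_empty <- function(K) rep(list(integer(0)), K + 1L)

#' Base entry vectors of the feasibility tables
#'
#' The three degenerate solution sets have fixed table semantics: the empty
#' solution contributes path-count set `{0}` at zero cycles; a single
#' alternating path contributes `{1}` at zero cycles; a single alternating
#' cycle contributes `{0}` at one cycle. `"none"` is the identically empty
#' vector (no solution).
#'
#' @param kind one of `"empty"`, `"path"`, `"cycle"`, `"none"`.
#' @param sigma_c_max largest cycle count tracked (vector has
#'   `sigma_c_max + 1` entries, for 0 cycles up to `sigma_c_max`).
#' @return An entry vector: list of integer sets indexed by cycle count.
#' @export
ev_base <- function(kind = c("empty", "path", "cycle", "none"), sigma_c_max) {
  kind <- match.arg(kind)
  K <- as.integer(sigma_c_max)
  v <- ev_empty(K)
  if (kind == "empty") v[[1L]] <- 0L
  if (kind == "path") v[[1L]] <- 1L
  if (kind == "cycle" && K >= 1L) v[[2L]] <- 0L
  v
}

ev_is_void <- function(a) all(lengths(a) == 0L)

ev_union <- function(...) {
  vs <- list(...)
  vs <- vs[!vapply(vs, is.null, logical(1))]
  K1 <- length(vs[[1L]])
  out <- vector("list", K1)
  for (k in seq_len(K1)) {
    out[[k]] <- sort(unique(unlist(lapply(vs, `[[`, k))))
  }
  out
}

# convolution over cycle counts with Minkowski sums of the path-count sets
ev_jux <- function(a, b) {
  K <- length(a) - 1L
  out <- ev_empty(K)
  for (i in 0:K) {
    if (length(a[[i + 1L]]) == 0L) next
    for (j in 0:(K - i)) {
      if (length(b[[j + 1L]]) == 0L) next
      k <- i + j
      out[[k + 1L]] <- c(out[[k + 1L]], outer(a[[i + 1L]], b[[j + 1L]], `+`))
    }
  }
  lapply(out, function(x) sort(unique(as.integer(x))))
}

ev_jux_all <- function(...) {
  vs <- list(...)
  vs <- vs[!vapply(vs, is.null, logical(1))]
  Reduce(ev_jux, vs)
}

# shift path counts by dp (dropping negatives) and cycle counts by dc
# (dropping overflow)
ev_shift <- function(a, dp = 0L, dc = 0L) {
  K <- length(a) - 1L
  out <- ev_empty(K)
  for (i in 0:K) {
    x <- a[[i + 1L]]
    if (length(x) == 0L) next
    k <- i + dc
    if (k < 0L || k > K) next
    x <- as.integer(x + dp)
    out[[k + 1L]] <- sort(unique(x[x >= 0L]))
  }
  out
}

#' Compose entry vectors
#'
#' Combines the entry vectors of solution sets over vertex-disjoint
#' subgraphs. `"juxtapose"` is plain convolution (path and cycle counts
#' add). `"merge"` with parameter `t` joins `t` alternating paths, one per
#' operand group, into a single path (path count drops by `t - 1`).
#' `"close"` with parameter `t` closes `t` paths into one alternating cycle
#' (path count drops by `t`, cycle count rises by one; with no cycle budget
#' the result is identically empty, not an error). `"absorb"` replaces an
#' absorbent edge by a path (path count drops by one).
#'
#' @param kind operation name.
#' @param vectors list of entry vectors (all of the same length).
#' @param t number of paths merged or closed (ignored otherwise).
#' @return The composed entry vector.
#' @export
ev_compose <- function(kind = c("juxtapose", "merge", "close", "absorb"),
                       vectors, t = length(vectors)) {
  kind <- match.arg(kind)
  stopifnot(length(vectors) >= 1L)
  out <- Reduce(ev_jux, vectors)
  switch(kind,
         juxtapose = out,
         merge = { stopifnot(t >= 1L); ev_shift(out, dp = -(t - 1L)) },
         close = { stopifnot(t >= 1L); ev_shift(out, dp = -t, dc = 1L) },
         absorb = ev_shift(out, dp = -1L))
}

# ---------------------------------------------------------------------------
# dynamic program over the rooted clique tree

dp_vertex <- function(v, cs, clique_tab, s_bridge_child, K) {
  kids <- cs$door_children[[v]]
  if (is.null(kids) || length(kids) == 0L) {
    return(list(F = ev_base("empty", K), E = ev_empty(K)))
  }
  all_of <- lapply(kids, function(k) {
    ev_union(clique_tab[[k]]$F, clique_tab[[k]]$E)
  })
  names(all_of) <- kids
  forced <- s_bridge_child[[v]]
  if (!is.null(forced)) {
    others <- setdiff(kids, forced)
    E <- ev_jux_all(clique_tab[[forced]]$E,
                    if (length(others)) Reduce(ev_jux, all_of[others])
                    else ev_base("empty", K))
    return(list(F = ev_empty(K), E = E))
  }
  F <- Reduce(ev_jux, all_of)
  E <- ev_empty(K)
  for (k in kids) {
    others <- setdiff(kids, k)
    E <- ev_union(E, ev_jux_all(
      clique_tab[[k]]$E,
      if (length(others)) Reduce(ev_jux, all_of[others])
      else ev_base("empty", K)))
  }
  list(F = F, E = E)
}

dp_element <- function(el, vtab, K) {
  if (el$type == "cycle") {
    F <- Reduce(ev_jux, c(list(ev_base("cycle", K)),
                          lapply(el$vertices, function(w) vtab[[w]]$F)))
    return(list(C = ev_empty(K), E = ev_empty(K), F = F, I = NULL))
  }
  u <- el$extremities[1L]; v <- el$extremities[2L]
  I <- if (length(el$inner)) {
    Reduce(ev_jux, lapply(el$inner, function(w) vtab[[w]]$F))
  } else ev_base("empty", K)
  base <- ev_jux(ev_base("path", K), I)
  C <- ev_jux_all(base, vtab[[u]]$F, vtab[[v]]$F)
  E <- ev_shift(ev_jux(base, ev_union(ev_jux(vtab[[u]]$E, vtab[[v]]$F),
                                      ev_jux(vtab[[u]]$F, vtab[[v]]$E))),
                dp = -1L)
  F <- ev_shift(ev_jux_all(base, vtab[[u]]$E, vtab[[v]]$E), dp = -2L)
  if (el$n_me >= 2L) {
    # the element's path closed into a cycle via the clique edge between its
    # extremities (a 2-vertex cycle would need a parallel edge, hence >= 2)
    F <- ev_union(F, ev_shift(ev_jux_all(base, vtab[[u]]$F, vtab[[v]]$F),
                              dp = -1L, dc = 1L))
  }
  list(C = C, E = E, F = F, I = I)
}

dp_mrg <- function(a, b) ev_shift(ev_jux(a, b), dp = -1L)
dp_cls <- function(a, b) ev_shift(ev_jux(a, b), dp = -2L, dc = 1L)
dp_abs <- function(a, b) ev_shift(ev_jux(a, b), dp = -1L)

# fold the alternating elements of a (sub)clique, maintaining the five
# solution classes: F frozen not absorbent, A frozen absorbent, Ap (one or
# more closeable paths, rest not extensible), E extensible not closeable,
# Ep (closeable plus an extensible path)
dp_subclique <- function(etabs, K) {
  F <- ev_base("empty", K)
  A <- Ap <- E <- Ep <- ev_empty(K)
  for (et in etabs) {
    Ce <- et$C; Ee <- et$E; Fe <- et$F
    F2 <- ev_jux(F, Fe)
    A2 <- ev_union(ev_jux(A, Fe), dp_mrg(E, Ee), dp_abs(A, Ce),
                   dp_cls(Ap, Ce))
    Ap2 <- ev_union(ev_jux(Ap, Fe), ev_jux(ev_union(F, A, Ap), Ce),
                    dp_mrg(Ep, Ee), dp_mrg(Ap, Ce))
    E2 <- ev_union(ev_jux(E, ev_union(Fe, Ee)), dp_mrg(E, Ce),
                   dp_mrg(Ep, Ee), dp_mrg(Ap, Ee), dp_cls(Ep, Ce),
                   ev_jux(ev_union(F, A), Ee))
    Ep2 <- ev_union(ev_jux(Ep, ev_union(Ce, Fe, Ee)), ev_jux(Ap, Ee),
                    ev_jux(E, Ce))
    F <- F2; A <- A2; Ap <- Ap2; E <- E2; Ep <- Ep2
  }
  list(F = F, A = A, Ap = Ap, E = E, Ep = Ep,
       C = ev_union(Ap, Ep))
}

dp_clique <- function(cid, cs, clique_tab, vtab, els, K) {
  d <- cs$upper_door[[cid]]
  di <- which(vapply(els, function(e) d %in% e$vertices, logical(1)))
  sub <- dp_subclique(lapply(els[-di], function(e) e$tab), K)
  sub_all <- ev_union(sub$F, sub$A, sub$Ap, sub$E, sub$Ep)
  sub_ext <- ev_union(sub$E, sub$Ap, sub$Ep)
  sub_close <- ev_union(sub$Ap, sub$Ep)
  sub_abs <- ev_union(sub$A, sub$Ap)
  el <- els[[di]]
  if (el$type == "cycle") {
    return(list(F = ev_jux(el$tab$F, sub_all), E = ev_empty(K)))
  }
  if (d %in% el$inner) {
    et <- el$tab
    Fc <- ev_union(ev_jux(ev_union(et$C, et$E, et$F), sub_all),
                   dp_mrg(ev_union(et$C, et$E), sub_ext),
                   dp_cls(et$C, sub_close),
                   dp_abs(et$C, sub_abs))
    return(list(F = Fc, E = ev_empty(K)))
  }
  # d is an extremity of the door element
  dd <- d
  dp_v <- setdiff(el$extremities, d)
  if (length(dp_v) == 0L) dp_v <- d  # degenerate, cannot happen on valid input
  I <- el$tab$I
  base <- ev_jux(ev_base("path", K), I)
  Fd <- vtab[[dd]]$F; Edv <- vtab[[dd]]$E
  Fo <- vtab[[dp_v]]$F; Eo <- vtab[[dp_v]]$E
  Ce <- ev_jux_all(base, Fd, Fo)
  Ed <- ev_shift(ev_jux_all(base, Fd, Eo), dp = -1L)   # door free
  Edp <- ev_shift(ev_jux_all(base, Edv, Fo), dp = -1L) # door consumed
  Fe <- ev_shift(ev_jux_all(base, Edv, Eo), dp = -2L)
  if (el$n_me >= 2L) {
    Fe <- ev_union(Fe, ev_shift(ev_jux_all(base, Fd, Fo), dp = -1L, dc = 1L))
  }
  Fc <- ev_union(ev_jux(ev_union(Fe, Edp), sub_all),
                 dp_mrg(Edp, sub_ext),
                 dp_mrg(Ed, sub_ext),
                 dp_mrg(Ce, sub_ext),
                 dp_cls(Ce, sub_close),
                 dp_abs(Ce, sub_abs))
  Ec <- ev_union(ev_jux(ev_union(Ce, Ed), sub_all),
                 dp_mrg(Ce, sub_ext))
  list(F = Fc, E = Ec)
}

# order cliques so every clique appears after all its descendants
postorder_cliques <- function(cs) {
  out <- character(0)
  walk <- function(cid) {
    for (ch in cs$children[[cid]]) walk(ch)
    out <<- c(out, cid)
  }
  walk(cs$root)
  out
}

cluster_dp <- function(g, cs, s, K) {
  se <- as_solution_edges(g, s)$edges
  sdeg <- table(factor(as.vector(se), levels = g$vertices))
  if (any(sdeg > 1L)) {
    stop("vertex '", g$vertices[which(sdeg > 1L)[1L]],
         "' is incident to two solution edges")
  }
  # bridge edges of s force the corresponding child extension
  s_bridge_child <- list()
  if (nrow(se)) {
    sk <- edge_keys(se)
    for (cid in names(cs$cliques)) {
      if (is.na(cs$parent[cid])) next
      bk <- edge_keys(as_edge_matrix(
        rbind(c(cs$parent_door[[cid]], cs$upper_door[[cid]])), "bridge"))
      if (bk %in% sk) {
        v <- cs$parent_door[[cid]]
        if (!is.null(s_bridge_child[[v]])) {
          stop("vertex '", v, "' carries two bridge edges of the solution")
        }
        s_bridge_child[[v]] <- cid
      }
    }
  }
  clique_tab <- list()
  root_classes <- NULL
  for (cid in postorder_cliques(cs)) {
    els <- clique_elements(cs, cid, se)
    vtab <- list()
    for (v in cs$cliques[[cid]]) {
      vtab[[v]] <- dp_vertex(v, cs, clique_tab, s_bridge_child, K)
    }
    for (i in seq_along(els)) {
      els[[i]]$tab <- dp_element(els[[i]], vtab, K)
    }
    if (cid == cs$root) {
      root_classes <- dp_subclique(lapply(els, function(e) e$tab), K)
    } else {
      clique_tab[[cid]] <- dp_clique(cid, cs, clique_tab, vtab, els, K)
    }
  }
  list(root = root_classes, cliques = clique_tab)
}

#' Eligible path counts of a connected cluster graph
#'
#' Runs the clique-tree dynamic program bottom-up and reports, for each
#' cycle count `0..sigma_c_max`, the exact set of path counts `sigma_p` for
#' which a full solution extending `s` exists. One call therefore answers
#' every feasibility query up to the given cycle budget.
#'
#' @param g a valid, connected `scaffold_graph` in the connected cluster
#'   class.
#' @param s partial solution (set of link edges), `NULL` for empty.
#' @param sigma_c_max largest cycle count of interest; defaults to
#'   `floor(|M*|/2)`, the maximum possible.
#' @param cs optional precomputed [build_cluster_structure()] result.
#' @return List of integer vectors; element `i+1` is the sorted set of
#'   feasible path counts with exactly `i` cycles.
#' @export
cluster_eligible_paths <- function(g, s = NULL, sigma_c_max = NULL,
                                   cs = NULL) {
  if (is.null(cs)) cs <- build_cluster_structure(g)
  if (is.null(sigma_c_max)) sigma_c_max <- n_matching(g) %/% 2L
  r <- cluster_dp(g, cs, s, as.integer(sigma_c_max))$root
  ev_union(r$F, r$A, r$Ap, r$E, r$Ep)
}

#' Feasibility on connected cluster graphs (dynamic programming)
#'
#' Decides in polynomial time whether the partial solution `s` extends to a
#' collection of exactly `sigma_p` alternating paths and `sigma_c`
#' alternating cycles, for a connected cluster scaffold graph with no
#' matching bridge between cliques (see [complete_to_class()] for arbitrary
#' graphs). This is the feasibility function that [greedy_scaffold()] uses
#' on the cluster class.
#'
#' @inheritParams cluster_eligible_paths
#' @param sigma_p,sigma_c requested numbers of alternating paths and cycles.
#' @return Logical scalar.
#' @export
feasible_cluster <- function(g, s = NULL, sigma_p, sigma_c, cs = NULL) {
  if (sigma_p < 0 || sigma_c < 0) return(FALSE)
  el <- cluster_eligible_paths(g, s, sigma_c_max = sigma_c, cs = cs)
  sigma_p %in% el[[sigma_c + 1L]]
}

# ---------------------------------------------------------------------------
# complete graphs

is_complete_scaffold <- function(g) {
  n <- length(g$vertices)
  nrow(g$matching) + nrow(g$links) == n * (n - 1L) / 2L
}

#' Feasibility on complete scaffold graphs (constant time)
#'
#' In a complete graph any two path extremities are adjacent, so feasibility
#' depends only on component statistics of `s` united with the matching:
#' with `c` cycles already closed, `P` path components (untouched matching
#' edges count as length-one paths), `M2` of them holding at least two
#' matching edges, and `k = sigma_c - c` cycles still to build, a solution
#' exists iff `c <= sigma_c`, `P >= sigma_p + k`,
#' `P + min(k, M2) >= sigma_p + 2k` (a cycle is closed either from one path
#' with two or more matching edges or from two paths joined; a lone
#' single-edge path cannot close), every path ends up somewhere
#' (`sigma_p + k >= 1` when `P > 0`), and `P = 0` forces
#' `sigma_p = k = 0`. The predicate is validated against the exhaustive
#' oracle on all complete instances with up to six matching edges.
#'
#' @param g a valid, complete `scaffold_graph`.
#' @param s partial solution, `NULL` for empty.
#' @param sigma_p,sigma_c requested path and cycle counts.
#' @return Logical scalar.
#' @export
feasible_complete <- function(g, s = NULL, sigma_p, sigma_c) {
  assert_valid_graph(g)
  if (!is_complete_scaffold(g)) {
    stop("feasible_complete: graph is not complete; use feasible_cluster ",
         "or complete_to_class first")
  }
  if (sigma_p < 0 || sigma_c < 0) return(FALSE)
  d <- decompose_solution(g, s, cover_all = TRUE)
  cc <- d$sigma_c
  P <- d$sigma_p
  M2 <- sum(vapply(d$paths, length, integer(1)) >= 4L)
  k <- sigma_c - cc
  if (k < 0L) return(FALSE)
  if (P == 0L) return(sigma_p == 0L && k == 0L)
  if (sigma_p + k < 1L) return(FALSE)
  if (P < sigma_p + k) return(FALSE)
  P + min(k, M2) >= sigma_p + 2L * k
}
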