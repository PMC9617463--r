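# Exact exponential-time solvers, used as ground truth on small instances.

# map a scaffold graph to the integer encoding of the C++ search:
# matching edge i covers vertices 2i-2, 2i-1 (0-based)
oracle_encode <- function(g) {
  vid <- integer(length(g$vertices))
  names(vid) <- c(t(g$matching))
  vid[] <- seq_len(2L * nrow(g$matching)) - 1L
  links <- cbind(vid[g$links[, 1L]], vid[g$links[, 2L]])
  storage.mode(links) <- "integer"
  list(n_me = nrow(g$matching), links = links, weights = g$weights, vid = vid)
}

oracle_cap_check <- function(g, cap, who) {
  n <- n_matching(g)
  if (n > cap) {
    stop(who, ": instance has ", n, " matching edges, above the cap of ", cap,
         "; the exhaustive search is exponential. Pass a larger `cap` ",
         "explicitly to force it.")
  }
}

oracle_run <- function(g, s, sigma_p, sigma_c, mode, prune = TRUE,
                       node_cap = 5e8) {
  enc <- oracle_encode(g)
  idx <- as_solution_edges(g, s)$index
  res <- oracle_search_cpp(enc$n_me, enc$links, enc$weights,
                           as.integer(idx - 1L),
                           as.integer(sigma_p), as.integer(sigma_c),
                           as.integer(mode), prune, node_cap)
  if (res$aborted) stop("oracle search exceeded its node budget")
  if (!res$forced_ok) {
    stop("the forced partial solution has a vertex with two link edges")
  }
  res
}

#' Exact feasibility by exhaustive search
#'
#' Decides by backtracking over all extensions of the partial solution `s`
#' whether the scaffold graph can be decomposed into exactly `sigma_p`
#' alternating paths and `sigma_c` alternating cycles containing `s`.
#' Exponential time; refuses instances above `cap` matching edges.
#'
#' @param g a valid `scaffold_graph`.
#' @param s partial solution (set of link edges), `NULL` for empty.
#' @param sigma_p,sigma_c target path and cycle counts.
#' @param cap maximum number of matching edges accepted.
#' @return Logical scalar.
#' @export
brute_force_feasible <- function(g, s = NULL, sigma_p, sigma_c, cap = 10L) {
  assert_valid_graph(g)
  oracle_cap_check(g, cap, "brute_force_feasible")
  if (sigma_p < 0 || sigma_c < 0) return(FALSE)
  if (sigma_p + 2 * sigma_c > n_matching(g)) return(FALSE)
  oracle_run(g, s, sigma_p, sigma_c, mode = 0L)$feasible
}

#' Exact maximum-weight solution by exhaustive search
#'
#' Enumerates all decompositions into exactly `sigma_p` alternating paths and
#' `sigma_c` alternating cycles (extending `s`, if given) and returns the
#' maximum total link weight together with a witness. With `prune = TRUE`
#' (default) branches whose admissible weight upper bound cannot strictly
#' improve the incumbent are discarded; the optimum is unaffected but
#' `enumeration_count` then under-reports the number of solutions. Use
#' `prune = FALSE` for exhaustive counting.
#'
#' @inheritParams brute_force_feasible
#' @param prune enable branch-and-bound weight pruning.
#' @return An object of class `oracle_result`: `feasible`, `best_weight`
#'   (`NA` if infeasible), `witness` (canonical link-edge matrix or `NULL`),
#'   and `enumeration_count`.
#' @export
brute_force_optimum <- function(g, s = NULL, sigma_p, sigma_c, cap = 10L,
                                prune = TRUE) {
  assert_valid_graph(g)
  oracle_cap_check(g, cap, "brute_force_optimum")
  res <- oracle_run(g, s, sigma_p, sigma_c, mode = 1L, prune = prune)
  witness <- NULL
  if (res$feasible) {
    witness <- g$links[sort(res$witness + 1L), , drop = FALSE]
  }
  structure(list(feasible = res$feasible,
                 best_weight = if (res$feasible) res$best_weight else NA_real_,
                 witness = witness,
                 enumeration_count = res$count),
            class = "oracle_result")
}

#' @export
print.oracle_result <- function(x, ...) {
  if (!x$feasible) {
    cat("Oracle: infeasible\n")
  } else {
    cat("Oracle: optimum weight ", x$best_weight, " (",
        x$enumeration_count, " solution(s) enumerated)\n", sep = "")
  }
  invisible(x)
}

#' Achievable (paths, cycles) profile by exhaustive search
#'
#' Enumerates every full solution extending `s` and tabulates how many
#' realise each pair (number of alternating paths, number of alternating
#' cycles). The profile is the exact ground truth against which the
#' polynomial feasibility functions are tested.
#'
#' @inheritParams brute_force_feasible
#' @return Integer-valued matrix with rows `0..|M*|` (paths) and columns
#'   `0..floor(|M*|/2)` (cycles); entry = number of solutions.
#' @export
brute_force_profile <- function(g, s = NULL, cap = 10L) {
  assert_valid_graph(g)
  oracle_cap_check(g, cap, "brute_force_profile")
  res <- oracle_run(g, s, 0L, 0L, mode = 2L)
  prof <- res$profile
  dimnames(prof) <- list(paths = 0:(nrow(prof) - 1L),
                         cycles = 0:(ncol(prof) - 1L))
  prof
}

#' Maximum independent set size of a simple graph
#'
#' Exact independence number, delegated to igraph's exact solver. Inputs
#' above `cap` vertices are refused since the problem is NP-hard and this
#' helper exists to certify small reduction instances.
#'
#' @param graph an `igraph` object (undirected, simple).
#' @param cap maximum number of vertices accepted.
#' @return Integer scalar.
#' @export
max_independent_set <- function(graph, cap = 20L) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::vcount(graph) > cap) {
    stop("max_independent_set: graph has ", igraph::vcount(graph),
         " vertices, above the cap of ", cap)
  }
  if (igraph::vcount(graph) == 0L) return(0L)
  as.integer(igraph::independence_number(graph))
}
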