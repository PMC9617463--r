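# Greedy maximum-weight scaffolding guarded by a feasibility function.

#' Greedy scaffolding
#'
#' Scans the link edges in non-increasing weight order (ties broken
#' lexicographically on the sorted endpoint pair) and adds an edge to the
#' partial solution whenever both endpoints are still free and the
#' feasibility function confirms that the enlarged solution still extends to
#' exactly `sigma_p` alternating paths and `sigma_c` alternating cycles.
#' When an edge is accepted, all other link edges at its endpoints are
#' discarded (the set R of the analysis). Because every feasibility function
#' here is downward monotone, the scan terminates with a complete valid
#' solution whenever the empty solution is feasible.
#'
#' @param g a valid `scaffold_graph` (connected cluster class for
#'   `feasibility = "cluster"`, complete for `"complete"`; see
#'   [complete_to_class()]).
#' @param sigma_p,sigma_c requested numbers of alternating paths and cycles.
#' @param feasibility `"cluster"`, `"complete"`, `"oracle"`, or a function
#'   `f(g, s, sigma_p, sigma_c)` returning a logical.
#' @param cs optional precomputed cluster structure (cluster class only).
#' @param oracle_cap matching-edge cap passed to the oracle guard.
#' @return A list of class `greedy_result`: `decomposition` (see
#'   [decompose_solution()]), `edges` (accepted link edges), `weight`, and
#'   `trace`, a data frame recording each considered edge with outcome
#'   `accepted`, `removed_incident` or `rejected_infeasible`.
#' @examples
#' g <- grid_2xk(2)$graph
#' greedy_scaffold(g, sigma_p = 1, sigma_c = 0, feasibility = "oracle")$weight
#' @export
greedy_scaffold <- function(g, sigma_p, sigma_c,
                            feasibility = c("cluster", "complete", "oracle"),
                            cs = NULL, oracle_cap = 12L) {
  assert_valid_graph(g)
  if (is.function(feasibility)) {
    guard <- function(se) feasibility(g, se, sigma_p, sigma_c)
  } else {
    feasibility <- match.arg(feasibility)
    guard <- switch(feasibility,
      cluster = {
        if (is.null(cs)) cs <- build_cluster_structure(g)
        function(se) feasible_cluster(g, se, sigma_p, sigma_c, cs = cs)
      },
      complete = function(se) feasible_complete(g, se, sigma_p, sigma_c),
      oracle = function(se) {
        brute_force_feasible(g, se, sigma_p, sigma_c, cap = oracle_cap)
      })
  }
  if (!guard(NULL)) {
    stop("infeasible instance: no collection of ", sigma_p, " paths and ",
         sigma_c, " cycles exists")
  }
  ord <- order(-g$weights, g$links[, 1L], g$links[, 2L])
  saturated <- stats::setNames(logical(length(g$vertices)), g$vertices)
  acc <- matrix(character(0), ncol = 2L)
  outcome <- character(length(ord))
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    u <- g$links[i, 1L]; v <- g$links[i, 2L]
    if (saturated[u] || saturated[v]) {
      outcome[pos] <- "removed_incident"
      next
    }
    cand <- rbind(acc, c(u, v))
    if (guard(cand)) {
      acc <- cand
      saturated[c(u, v)] <- TRUE
      outcome[pos] <- "accepted"
    } else {
      outcome[pos] <- "rejected_infeasible"
    }
  }
  d <- decompose_solution(g, acc, cover_all = TRUE)
  if (d$sigma_p != sigma_p || d$sigma_c != sigma_c) {
    stop("internal error: greedy terminated with ", d$sigma_p, " paths and ",
         d$sigma_c, " cycles instead of (", sigma_p, ", ", sigma_c, ")")
  }
  trace <- data.frame(u = g$links[ord, 1L], v = g$links[ord, 2L],
                      weight = g$weights[ord], outcome = outcome,
                      stringsAsFactors = FALSE)
  structure(list(decomposition = d, edges = d$edges, weight = d$weight,
                 trace = trace),
            class = "greedy_result")
}

#' @export
print.greedy_result <- function(x, ...) {
  cat("Greedy scaffold solution: weight ", x$weight, ", ",
      x$decomposition$sigma_p, " path(s), ", x$decomposition$sigma_c,
      " cycle(s)\n", sep = "")
  invisible(x)
}

#' Compare greedy feasibility classes against the exact optimum
#'
#' For each instance bundle, runs the greedy algorithm under the requested
#' feasibility classes (completing the graph into the class first where
#' needed) and, when the instance is small enough for the oracle, the exact
#' optimum of the same completed graph, reporting the optimum-to-greedy
#' weight ratio.
#'
#' @param instances list of instance bundles (see [random_instance()]).
#' @param classes subset of `"complete"`, `"cluster"`, `"oracle"`.
#' @param oracle_cap matching-edge cap for the exact optimum.
#' @return A data frame with one row per instance and class: `instance`,
#'   `class`, `greedy`, `opt`, `ratio` (NA where the oracle was skipped or
#'   the greedy weight is zero).
#' @export
run_comparison <- function(instances,
                           classes = c("complete", "cluster", "oracle"),
                           oracle_cap = 10L) {
  classes <- match.arg(classes, several.ok = TRUE)
  rows <- list()
  for (ii in seq_along(instances)) {
    inst <- instances[[ii]]
    for (cl in classes) {
      gg <- switch(cl,
                   complete = complete_to_class(inst$graph, "complete"),
                   cluster = complete_to_class(inst$graph, "cluster"),
                   oracle = inst$graph)
      gr <- greedy_scaffold(gg, inst$sigma_p, inst$sigma_c, feasibility = cl,
                            oracle_cap = oracle_cap)
      opt <- NA_real_
      if (n_matching(gg) <= oracle_cap) {
        opt <- brute_force_optimum(gg, sigma_p = inst$sigma_p,
                                   sigma_c = inst$sigma_c,
                                   cap = oracle_cap)$best_weight
      }
      rows[[length(rows) + 1L]] <- data.frame(
        instance = ii, class = cl, greedy = gr$weight, opt = opt,
        ratio = if (!is.na(opt) && gr$weight > 0) opt / gr$weight else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
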