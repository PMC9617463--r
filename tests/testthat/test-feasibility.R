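test_that("entry-vector composition follows the table algebra", {
  K <- 2
  p <- ev_base("path", K)
  # juxtaposition with the empty-solution vector is the identity
  e0 <- ev_base("empty", K)
  expect_identical(ev_compose("juxtapose", list(p, e0)), p)
  # merging two single paths leaves one path
  expect_identical(ev_compose("merge", list(p, p), t = 2)[[1]], 1L)
  # closing two single paths yields one cycle, zero paths
  cl <- ev_compose("close", list(p, p), t = 2)
  expect_identical(cl[[1]], integer(0))
  expect_identical(cl[[2]], 0L)
  # closing with no cycle budget is empty, not an error
  expect_true(all(lengths(ev_compose("close", list(ev_base("path", 0)),
                                     t = 1)) == 0))
  # juxtaposition is commutative and associative
  c1 <- ev_base("cycle", K)
  ab <- ev_compose("juxtapose", list(p, c1))
  ba <- ev_compose("juxtapose", list(c1, p))
  expect_identical(ab, ba)
  expect_identical(ev_compose("juxtapose", list(ab, p)),
                   ev_compose("juxtapose", list(p, ab)))
})

test_that("cluster feasibility matches the oracle on handcrafted graphs", {
  g <- k2_graph()
  expect_true(feasible_cluster(g, NULL, 1, 0))
  expect_false(feasible_cluster(g, NULL, 0, 1))

  # leaf K4 clique below a K2 root: profile equivalence including partials
  g2 <- scaffold_graph(
    rbind(c("a", "b"), c("c", "d"), c("e", "f")),
    rbind(c("c", "e"), c("c", "f"), c("d", "e"), c("d", "f"), c("b", "c")),
    rep(1, 5))
  expect_profile_equiv(g2)
  expect_profile_equiv(g2, rbind(c("b", "c")))      # forced bridge
  expect_profile_equiv(g2, rbind(c("d", "e")))      # intra-clique element
})

test_that("the DP is invariant under vertex relabeling", {
  set.seed(41)
  for (s in 1:6) {
    b <- random_instance("cluster", seed = s + 900, min_me = 3, max_me = 6)
    g <- b$graph
    el1 <- cluster_eligible_paths(g)
    # relabel vertices with a random permutation (reverses element order)
    perm <- sample(length(g$vertices))
    map <- stats::setNames(sprintf("z%03d", perm), g$vertices)
    relab <- function(m) matrix(unname(map[m]), ncol = 2)
    g2 <- scaffold_graph(relab(g$matching), relab(g$links), g$weights)
    el2 <- cluster_eligible_paths(g2)
    expect_identical(el1, el2)
  }
})

test_that("feasibility is downward monotone in the partial solution", {
  set.seed(51)
  for (s in 1:10) {
    b <- random_instance("cluster", seed = s + 130, min_me = 3, max_me = 6)
    g <- b$graph
    sol <- random_partial_solution(g, target = 3)
    if (is.null(sol) || nrow(sol) < 1) next
    sub <- sol[-1, , drop = FALSE]
    for (ci in 0:(n_matching(g) %/% 2)) {
      full <- cluster_eligible_paths(g, sol)[[ci + 1]]
      less <- cluster_eligible_paths(g, sub)[[ci + 1]]
      expect_true(all(full %in% less))
    }
  }
})

test_that("complete-graph feasibility agrees with the oracle exhaustively", {
  set.seed(61)
  for (n in 1:6) {
    for (rep in 1:8) {
      b <- random_instance("complete", seed = n * 1000 + rep,
                           min_me = n, max_me = n)
      g <- b$graph
      sol <- random_partial_solution(g)
      prof <- brute_force_profile(g, sol, cap = 6)
      for (p in 0:n) {
        for (ci in 0:(n %/% 2)) {
          expect_equal(feasible_complete(g, sol, p, ci),
                       prof[p + 1, ci + 1] > 0,
                       label = sprintf("n=%d p=%d c=%d", n, p, ci))
        }
      }
    }
  }
})

test_that("complete-graph feasibility covers the textbook cases", {
  b3 <- random_instance("complete", seed = 1, min_me = 3, max_me = 3)
  expect_true(feasible_complete(b3$graph, NULL, 1, 1))
  b2 <- random_instance("complete", seed = 1, min_me = 2, max_me = 2)
  expect_false(feasible_complete(b2$graph, NULL, 0, 2))
  expect_true(feasible_complete(b2$graph, NULL, 0, 1))
  expect_error(feasible_complete(two_k4 <- k2_graph(), NULL, 1, 0), NA)
  g4 <- four_cycle_graph()
  expect_error(feasible_complete(g4, NULL, 1, 0), "not complete")
})

test_that("a lone single-matching-edge path cannot close into a cycle", {
  # component sizes [3,1,1] with one path and two cycles requested: the
  # counting conditions alone would pass, the structural predicate must not
  b <- random_instance("complete", seed = 9, min_me = 5, max_me = 5)
  g <- b$graph
  # build a partial solution chaining three matching edges into one path
  me <- g$matching
  chain <- rbind(c(me[1, 2], me[2, 1]), c(me[2, 2], me[3, 1]))
  expect_equal(feasible_complete(g, chain, 1, 2),
               brute_force_feasible(g, chain, 1, 2, cap = 5))
  expect_false(feasible_complete(g, chain, 1, 2))
})
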