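two_k4_bridge <- function() {
  scaffold_graph(
    rbind(c("a", "b"), c("c", "d"), c("e", "f"), c("g", "h")),
    rbind(c("a", "c"), c("a", "d"), c("b", "c"), c("b", "d"),
          c("e", "g"), c("e", "h"), c("f", "g"), c("f", "h"),
          c("d", "e")),
    c(rep(1, 8), 2))
}

test_that("bridges are exactly the cut edges", {
  g <- two_k4_bridge()
  expect_identical(find_bridges(g), rbind(c("d", "e")))

  # a path on 4 vertices: every edge is a bridge
  p4 <- scaffold_graph(rbind(c("a", "b"), c("c", "d")), rbind(c("b", "c")), 1)
  expect_equal(nrow(find_bridges(p4)), 3)

  # the 4-cycle has none
  expect_equal(nrow(find_bridges(four_cycle_graph())), 0)
})

test_that("cluster structures are recognised, rooted and doored", {
  cs <- build_cluster_structure(two_k4_bridge())
  expect_equal(length(cs$cliques), 2)
  expect_equal(cs$root, cs$clique_of[["a"]])
  child <- setdiff(names(cs$cliques), cs$root)
  expect_equal(unname(cs$upper_door[child]), "e")
  expect_equal(unname(cs$parent_door[child]), "d")

  # with an explicit root, orientation flips
  cs2 <- build_cluster_structure(two_k4_bridge(), root = "g")
  expect_equal(cs2$root, cs2$clique_of[["g"]])
  expect_equal(unname(cs2$upper_door[setdiff(names(cs2$cliques), cs2$root)]),
               "d")

  # a 4-cycle is bridgeless but no clique: rejected with a witness pair
  expect_error(build_cluster_structure(four_cycle_graph()),
               "not a connected cluster graph")
})

test_that("alternating elements split a clique along the partial solution", {
  g <- two_k4_bridge()
  cs <- build_cluster_structure(g)
  child <- setdiff(names(cs$cliques), cs$root)

  # empty solution: every matching edge is its own single-edge element
  a0 <- alternating_elements_of(cs, cs$root, NULL)
  expect_equal(length(a0$elements), 2)
  expect_true(all(vapply(a0$elements, function(e) e$n_me, numeric(1)) == 1))
  expect_null(a0$subclique)  # root has no upper door

  # a merged pair inside the child clique forms one 2-matching-edge element;
  # its vertices are excluded from the subclique
  a1 <- alternating_elements_of(cs, child, rbind(c("f", "g")))
  lens <- sort(vapply(a1$elements, function(e) e$n_me, numeric(1)))
  expect_equal(lens, c(2))
  expect_equal(a1$subclique, character(0))

  a2 <- alternating_elements_of(cs, child, NULL)
  expect_equal(a2$subclique, setdiff(cs$cliques[[child]],
                                     a2$elements[[a2$door_element]]$vertices))
})

test_that("completion adds only zero-weight links and reaches the class", {
  # 4-cycle completed to the cluster class becomes K4
  g4 <- four_cycle_graph()
  gc <- complete_to_class(g4, "cluster")
  expect_true(validate_graph(gc)$ok)
  expect_equal(nrow(gc$links), 4)  # two zero-weight chords added
  expect_equal(sum(gc$weights), sum(g4$weights))
  expect_silent(build_cluster_structure(gc))

  # already complete: identity
  b <- random_instance("complete", seed = 3, min_me = 3, max_me = 4)
  expect_identical(complete_to_class(b$graph, "complete"), b$graph)

  # matching bridge between two K2 components: merged into one clique
  g <- scaffold_graph(rbind(c("a", "b"), c("c", "d"), c("e", "f")),
                      rbind(c("b", "c"), c("d", "e")), c(1, 1))
  gc2 <- complete_to_class(g, "cluster")
  expect_silent(cs <- build_cluster_structure(gc2))
  expect_true(validate_graph(gc2)$ok)

  # disconnected input: connected by a zero-weight chain first
  gd <- scaffold_graph(rbind(c("a", "b"), c("c", "d")))
  gdc <- complete_to_class(gd, "cluster")
  expect_silent(build_cluster_structure(gdc))
})

test_that("completion preserves every solution and its weight", {
  set.seed(31)
  for (s in 1:6) {
    b <- random_instance("cluster", seed = s + 70, min_me = 3, max_me = 6)
    g <- b$graph
    gc <- complete_to_class(g, "complete")
    sol <- random_partial_solution(g, target = 2)
    d1 <- decompose_solution(g, sol)
    d2 <- decompose_solution(gc, sol)
    expect_equal(d1$weight, d2$weight)
    expect_equal(d1$sigma_p, d2$sigma_p)
    # optimal weight is non-decreasing under completion
    o1 <- brute_force_optimum(g, sigma_p = b$sigma_p, sigma_c = b$sigma_c,
                              cap = 8)
    o2 <- brute_force_optimum(gc, sigma_p = b$sigma_p, sigma_c = b$sigma_c,
                              cap = 8)
    expect_gte(o2$best_weight, o1$best_weight)
  }
})
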