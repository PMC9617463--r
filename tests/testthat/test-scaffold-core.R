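test_that("validation accepts minimal scaffold graphs and names violations", {
  expect_true(validate_graph(k2_graph())$ok)
  expect_true(validate_graph(four_cycle_graph())$ok)

  odd <- scaffold_graph(rbind(c("a", "b")), vertices = c("a", "b", "z"))
  rep <- validate_graph(odd)
  expect_false(rep$ok)
  expect_true(any(grepl("perfect matching", rep$violations)) ||
                any(grepl("not covered", rep$violations)))

  neg <- scaffold_graph(rbind(c("a", "b"), c("c", "d")),
                        rbind(c("b", "c")), -1)
  expect_false(validate_graph(neg)$ok)

  dup <- scaffold_graph(rbind(c("a", "b")), rbind(c("a", "b")), 1)
  expect_false(validate_graph(dup)$ok)
})

test_that("decomposition splits a solution into canonical paths and cycles", {
  # empty solution on 5 matching edges: 5 length-one paths
  m5 <- scaffold_graph(matrix(paste0("v", 1:10), ncol = 2, byrow = TRUE),
                       rbind(c("v2", "v3")), 0)
  d <- decompose_solution(m5, NULL)
  expect_equal(d$sigma_p, 5)
  expect_equal(d$sigma_c, 0)
  expect_equal(d$weight, 0)

  # the 4-cycle closed by both link edges: one alternating cycle
  d4 <- decompose_solution(four_cycle_graph(), rbind(c("b", "c"), c("a", "d")))
  expect_equal(d4$sigma_p, 0)
  expect_equal(d4$sigma_c, 1)
  expect_equal(d4$cycles[[1]][1], "a")  # canonical rotation

  # 2x4 grid with the forced solution of the adversarial example: one path
  b <- grid_2xk(4, adversarial_weights = TRUE)
  s <- rbind(c("x01", "x02"), c("x03", "x04"), c("y02", "y03"))
  dg <- decompose_solution(b$graph, s)
  expect_equal(dg$sigma_p, 1)
  expect_equal(dg$sigma_c, 0)

  # a vertex with two solution edges is a structural error naming the vertex
  g3 <- grid_2xk(3)$graph
  expect_error(
    decompose_solution(g3, rbind(c("x01", "x02"), c("x02", "x03"))),
    "two solution edges")
})

test_that("decomposition is stable under re-decomposition of its own edges", {
  set.seed(11)
  for (s in 1:10) {
    b <- random_instance("cluster", seed = s, min_me = 3, max_me = 6)
    sol <- random_partial_solution(b$graph)
    d1 <- decompose_solution(b$graph, sol)
    d2 <- decompose_solution(b$graph, d1$edges)
    expect_equal(d1$sigma_p, d2$sigma_p)
    expect_equal(d1$sigma_c, d2$sigma_c)
    expect_equal(d1$weight, d2$weight)
  }
})

test_that("solution_is_valid checks exact path and cycle counts", {
  g <- k2_graph()
  expect_true(solution_is_valid(g, NULL, 1, 0))
  expect_false(solution_is_valid(g, NULL, 0, 1))
  b <- tightness_instance()
  expect_true(solution_is_valid(b$graph, b$provenance$optimal_edges, 3, 0))
  expect_false(solution_is_valid(b$graph, b$provenance$optimal_edges, 2, 1))
})

test_that("alternating girth matches exhaustive subset enumeration", {
  expect_equal(alternating_girth(four_cycle_graph()), 2)
  expect_true(is.infinite(alternating_girth(k2_graph())))

  # independent oracle: enumerate all solutions, take the smallest cycle
  set.seed(21)
  for (s in 1:8) {
    b <- random_instance("cluster", seed = s + 300, min_me = 2, max_me = 5)
    g <- b$graph
    best <- Inf
    m <- nrow(g$links)
    for (mask in 0:(2^m - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
      sm <- g$links[idx, , drop = FALSE]
      if (nrow(sm) && anyDuplicated(as.vector(sm))) next
      d <- decompose_solution(g, sm, cover_all = FALSE)
      for (cyc in d$cycles) best <- min(best, length(cyc) / 2)
    }
    expect_equal(alternating_girth(g), best)
  }
})

test_that("the girth search refuses oversized graphs unless forced", {
  b <- construction_sparse(mk_igraph(2, c(1, 2)), ell = 3)
  expect_equal(alternating_girth(b$graph), 3)
  expect_error(alternating_girth(b$graph, cap = 2), "cap")
})
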