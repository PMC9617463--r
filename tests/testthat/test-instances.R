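test_that("the sparse construction has the advertised shape", {
  # single edge: 1 edge gadget + 2 fillers per endpoint = 5 matching edges
  b <- construction_sparse(mk_igraph(2, c(1, 2)), ell = 3)
  expect_equal(n_matching(b$graph), 5)
  expect_true(validate_graph(b$graph)$ok)
  expect_equal(alternating_girth(b$graph), 3)

  # bipartite by the u / u-bar sides
  ig <- igraph::graph_from_edgelist(
    as.matrix(rbind(b$graph$matching, b$graph$links)), directed = FALSE)
  expect_true(igraph::bipartite_mapping(ig)$res)

  # raising ell raises the alternating girth
  p3 <- mk_igraph(3, c(1, 2, 2, 3))
  expect_equal(alternating_girth(construction_sparse(p3, ell = 4)$graph), 4)

  # preconditions are enforced
  expect_error(construction_sparse(mk_igraph(4, c(1,2,1,3,1,4,2,3,2,4,3,4))),
               "girth")
  star5 <- mk_igraph(5, c(1,2, 1,3, 1,4, 1,5))
  expect_error(construction_sparse(star5), "subcubic")
})

test_that("vertex-cycle feasibility encodes the independence number", {
  p3 <- mk_igraph(3, c(1, 2, 2, 3))
  b <- construction_sparse(p3, ell = 3)
  mis <- max_independent_set(p3)
  expect_equal(mis, 2)
  for (k in 0:3) {
    pr <- construction_sparse_params(b, k)
    expect_equal(
      brute_force_feasible(b$graph, NULL, pr$sigma_p, pr$sigma_c, cap = 12),
      mis >= k)
  }
})

test_that("every cycle of a sparse-construction solution is a vertex-cycle", {
  p3 <- mk_igraph(3, c(1, 2, 2, 3))
  b <- construction_sparse(p3, ell = 3)
  g <- b$graph
  pr <- construction_sparse_params(b, 2)
  opt <- brute_force_optimum(g, sigma_p = pr$sigma_p, sigma_c = pr$sigma_c,
                             cap = 12)
  expect_true(opt$feasible)
  d <- decompose_solution(g, opt$witness)
  expect_equal(d$sigma_c, 2)
  for (cyc in d$cycles) expect_equal(length(cyc) / 2, 3)
})

test_that("the poly-APX construction reproduces the printed example", {
  demo4 <- mk_igraph(4, c(1, 2, 2, 3, 1, 3, 1, 4, 3, 4))
  b <- construction_polyapx(demo4)
  expect_equal(n_matching(b$graph), 23)  # 3 per edge + 2 per vertex
  expect_equal(b$sigma_c, 9)
  expect_true(validate_graph(b$graph)$ok)
  # the long vertex-cycle of the second vertex visits exactly the 8 printed
  # gadget vertices
  expect_setequal(b$provenance$long_cycles[[2]],
                  c("v002_1", "vb002_1", "u001_002", "ub001_002",
                    "u002_002", "ub002_002", "v002_2", "vb002_2"))
  # each long vertex-cycle carries total weight one
  keys <- paste(b$graph$links[, 1], b$graph$links[, 2])
  for (t in seq_along(b$provenance$long_cycles)) {
    vs <- b$provenance$long_cycles[[t]]
    inside <- b$graph$links[, 1] %in% vs & b$graph$links[, 2] %in% vs
    # restrict to consecutive cycle edges: weight of the whole induced link
    # set minus clique chords; the single weight-1 edge sits on the cycle
    expect_equal(sum(b$graph$weights[inside]), 1)
  }
})

test_that("the tightness instance certifies the ratio of five", {
  b <- tightness_instance()
  expect_true(validate_graph(b$graph)$ok)
  cs <- build_cluster_structure(b$graph)
  expect_equal(length(cs$cliques), 4)
  gr <- greedy_scaffold(b$graph, 3, 0, feasibility = "cluster", cs = cs)
  expect_equal(gr$weight, 1)
  opt <- brute_force_optimum(b$graph, sigma_p = 3, sigma_c = 0, cap = 8)
  expect_equal(opt$best_weight, 5)
  expect_true(solution_is_valid(b$graph, opt$witness, 3, 0))
})

test_that("grids have the expected arithmetic and cycles", {
  b <- grid_2xk(4)
  expect_equal(length(b$graph$vertices), 8)
  expect_equal(n_matching(b$graph), 4)
  expect_equal(nrow(b$graph$links), 6)  # 2 rows of k-1 rungs
  b2 <- grid_2xk(2)
  expect_true(brute_force_feasible(b2$graph, NULL, 0, 1))
})

test_that("random generators are deterministic and land in their class", {
  b1 <- random_instance("cluster", seed = 123)
  b2 <- random_instance("cluster", seed = 123)
  expect_identical(b1$graph, b2$graph)
  expect_identical(b1$sigma_p, b2$sigma_p)
  expect_silent(build_cluster_structure(b1$graph))
  expect_true(brute_force_feasible(b1$graph, NULL, b1$sigma_p, b1$sigma_c,
                                   cap = 8))

  bc <- random_instance("complete", seed = 11)
  expect_true(validate_graph(bc$graph)$ok)
  expect_equal(nrow(bc$graph$links) + n_matching(bc$graph),
               choose(length(bc$graph$vertices), 2))

  bs <- random_instance("subcubic_trianglefree", seed = 7)
  ig <- bs$provenance$graph
  expect_lte(max(igraph::degree(ig)), 3)
  gi <- igraph::girth(ig)$girth
  if (length(gi) == 0 || is.na(gi)) gi <- Inf
  expect_gt(gi, 3)
})
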