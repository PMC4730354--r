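# inter-set average shortest-path distance and its permutation null

path_net <- function() {
  ppi_network(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")))
}

test_that("breadth-first distances are exact on a path graph", {
  D <- shortest_path_lengths_from(gene_set("A"), path_net())
  expect_equal(D["A", c("A", "B", "C", "D")], c(A = 0, B = 1, C = 2, D = 3))
})

test_that("unreachable nodes have infinite distance across components", {
  net <- ppi_network(data.frame(from = c("A", "C"), to = c("B", "D")))
  D <- shortest_path_lengths_from(gene_set("A"), net)
  expect_true(all(is.infinite(D["A", c("C", "D")])))
  expect_error(shortest_path_lengths_from(gene_set("ZZZ"), net),
               "no mapped source nodes")
})

test_that("distances agree with a Floyd-Warshall oracle on random graphs", {
  for (seed in 1:4) {
    net <- random_test_network(40, p = 0.06, seed = seed)
    D <- shortest_path_lengths_from(gene_set(network_nodes(net)), net)
    oracle <- bf_all_pairs(net)
    expect_equal(D[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("the average distance matches hand-counted and identity cases", {
  r <- average_shortest_distance(gene_set("A"), gene_set(c("C", "D")),
                                 path_net())
  expect_equal(r$dis_observed, 2.5)
  expect_equal(r$pair_count_used, 2)
  expect_equal(r$excluded_pairs, 0)

  same <- average_shortest_distance(gene_set("A"), gene_set("A"), path_net())
  expect_equal(same$dis_observed, 0)
})

test_that("the average distance equals the brute-force submatrix mean", {
  for (seed in 1:4) {
    net <- random_test_network(60, p = 0.05, seed = seed)
    nodes <- network_nodes(net)
    withr::with_seed(seed + 50, {
      a <- sample(nodes, 5)
      b <- sample(nodes, 7)
    })
    oracle <- bf_all_pairs(net)[a, b]
    r <- average_shortest_distance(gene_set(a), gene_set(b), net)
    expect_equal(r$dis_observed, mean(oracle[is.finite(oracle)]),
                 tolerance = 1e-12)
  }
})

test_that("the statistic is symmetric in its two sets under both policies", {
  net <- random_test_network(30, p = 0.05, seed = 11)
  nodes <- network_nodes(net)
  a <- gene_set(nodes[1:4]); b <- gene_set(nodes[10:16])
  for (policy in c("exclude", "penalize")) {
    expect_equal(
      average_shortest_distance(a, b, net, unreachable_policy = policy)$dis_observed,
      average_shortest_distance(b, a, net, unreachable_policy = policy)$dis_observed)
  }
})

test_that("adding an edge never increases the average distance", {
  net <- random_test_network(25, p = 0.05, seed = 13)
  nodes <- network_nodes(net)
  a <- gene_set(nodes[1:4]); b <- gene_set(nodes[15:20])
  base <- average_shortest_distance(a, b, net)$dis_observed
  ed <- network_edges(net)
  withr::with_seed(7, {
    for (k in 1:10) {
      new_edge <- sample(nodes, 2)
      net2 <- ppi_network(rbind(as.data.frame(ed),
                                data.frame(from = new_edge[1], to = new_edge[2])))
      expect_lte(average_shortest_distance(a, b, net2)$dis_observed, base)
    }
  })
})

test_that("pairs with no path are excluded or penalized as configured", {
  # two components: A-B and C-D
  net <- ppi_network(data.frame(from = c("A", "C"), to = c("B", "D")))
  r <- average_shortest_distance(gene_set(c("A", "C")), gene_set(c("B", "D")), net)
  expect_equal(r$excluded_pairs, 2)
  expect_equal(r$pair_count_used + r$excluded_pairs, 4)
  expect_equal(r$dis_observed, 1)

  pen <- average_shortest_distance(gene_set(c("A", "C")), gene_set(c("B", "D")),
                                   net, unreachable_policy = "penalize")
  expect_equal(pen$excluded_pairs, 0)
  expect_equal(pen$dis_observed, mean(c(1, 1, 2, 2)))  # diameter 1 -> penalty 2

  expect_error(
    average_shortest_distance(gene_set("A"), gene_set(c("C", "D")), net),
    "no finite pairs")
})

test_that("a degenerate permutation null keeps p valid and flags the z-score", {
  # complete graph: every resample of the full node set equals itself
  nodes <- LETTERS[1:5]
  cmb <- t(combn(nodes, 2))
  net <- ppi_network(data.frame(from = cmb[, 1], to = cmb[, 2]))
  expect_warning(
    pt <- permutation_test_proximity(gene_set(nodes), gene_set(nodes), net,
                                     randomized_side = "b",
                                     n_permutations = 100, seed = 5),
    "zero spread")
  expect_true(is.na(pt$z_score))
  expect_equal(pt$p_empirical, (100 + 1) / (100 + 1), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical permutation results", {
  net <- random_test_network(40, p = 0.08, seed = 21)
  nodes <- network_nodes(net)
  a <- gene_set(nodes[1:5]); b <- gene_set(nodes[20:28])
  p1 <- permutation_test_proximity(a, b, net, "b", 200, seed = 42)
  p2 <- permutation_test_proximity(a, b, net, "b", 200, seed = 42)
  expect_identical(p1, p2)
  p3 <- permutation_test_proximity(a, b, net, "b", 200, seed = 43)
  expect_false(identical(p1$null_values, p3$null_values))
})

test_that("the permutation test respects a restricted sampling universe", {
  net <- random_test_network(40, p = 0.08, seed = 22)
  nodes <- network_nodes(net)
  a <- gene_set(nodes[1:5])
  b <- gene_set(nodes[10:14])
  universe <- gene_set(nodes[10:20])
  pt <- permutation_test_proximity(a, b, net, "b", 100, seed = 1,
                                   sampling_universe = universe)
  expect_s3_class(pt, "permutation_result")
  expect_error(
    permutation_test_proximity(a, b, net, "b", 100, seed = 1,
                               sampling_universe = gene_set(nodes[10:12])),
    "universe smaller")
})

test_that("the degree-binned null runs and differs from the uniform null", {
  net <- random_test_network(50, p = 0.1, seed = 30)
  nodes <- network_nodes(net)
  a <- gene_set(nodes[1:6]); b <- gene_set(nodes[30:38])
  pu <- permutation_test_proximity(a, b, net, "b", 150, seed = 9)
  pd <- permutation_test_proximity(a, b, net, "b", 150, seed = 9,
                                   null_model = "degree_binned")
  expect_equal(pd$null_model, "degree_binned")
  expect_false(identical(pu$null_values, pd$null_values))
})
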