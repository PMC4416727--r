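test_that("gift logs condense into weighted directed flow edges", {
  empty <- build_flow_network(data.frame(year = integer(0), giver = integer(0),
                                         receiver = integer(0),
                                         amount = numeric(0)), 10)
  expect_equal(nrow(empty$edges), 0)
  # repeated gifts collapse onto one edge with the event count as weight
  g <- data.frame(year = c(3L, 9L, 4L), giver = c(1L, 1L, 2L),
                  receiver = c(2L, 2L, 1L), amount = c(5, 7, 3))
  fl <- build_flow_network(g, 5)
  expect_equal(nrow(fl$edges), 2)           # a->b and b->a stay distinct
  expect_equal(fl$weight[fl$edges[, 1] == 1], 2L)
  expect_error(build_flow_network(data.frame(year = 1L, giver = 9L,
                                             receiver = 1L, amount = 1), 5))
})

test_that("average path length matches hand counts and a BFS oracle", {
  expect_equal(average_path_length(flow_from_edges(5, cbind(1L, 2L))), 1)
  # path a-b-c: distances 1, 1, 2
  path3 <- flow_from_edges(5, cbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(average_path_length(path3), 4 / 3)
  expect_equal(average_path_length(flow_from_edges(4, cbind(integer(0),
                                                            integer(0)))), 0)
  set.seed(21)
  for (r in 1:50) {
    ed <- random_digraph_edges(8, 0.2)
    fl <- flow_from_edges(8, ed)
    keep <- sort(unique(as.integer(fl$edges)))
    if (length(keep) < 2) next
    und <- unique(cbind(pmin(fl$edges[, 1], fl$edges[, 2]),
                        pmax(fl$edges[, 1], fl$edges[, 2])))
    d <- bfs_distances(8, und)[keep, keep]
    d <- d[upper.tri(d)]
    d <- d[is.finite(d) & d > 0]
    expect_equal(average_path_length(fl), mean(d))
  }
})

test_that("average degree counts in plus out over non-isolated nodes", {
  expect_equal(average_degree(flow_from_edges(9, cbind(1L, 2L))), 1)
  expect_equal(average_degree(flow_from_edges(9, matrix(integer(0), 0, 2))), 0)
  set.seed(22)
  ed <- random_digraph_edges(10, 0.25)
  fl <- flow_from_edges(10, ed)
  keep <- unique(as.integer(fl$edges))
  expect_equal(average_degree(fl), 2 * nrow(fl$edges) / length(keep))
})

test_that("clustering matches a brute-force triangle census", {
  tri <- flow_from_edges(3, cbind(c(1L, 2L, 3L), c(2L, 3L, 1L)))
  expect_equal(clustering_coefficient(tri), 1)
  star <- flow_from_edges(4, cbind(rep(1L, 3), 2:4))
  expect_equal(clustering_coefficient(star), 0)
  set.seed(23)
  for (r in 1:50) {
    ed <- random_digraph_edges(8, 0.25)
    fl <- flow_from_edges(8, ed)
    keep <- sort(unique(as.integer(fl$edges)))
    if (length(keep) == 0) next
    und <- unique(cbind(pmin(fl$edges[, 1], fl$edges[, 2]),
                        pmax(fl$edges[, 1], fl$edges[, 2])))
    und <- und[und[, 1] != und[, 2], , drop = FALSE]
    expect_equal(clustering_coefficient(fl),
                 census_clustering(8, und, keep))
  }
})

test_that("cycle counts match exhaustive enumeration on small digraphs", {
  tri <- flow_from_edges(3, cbind(c(1L, 2L, 3L), c(2L, 3L, 1L)))
  expect_equal(count_cycles(tri, "simple_directed"), 1L)
  expect_equal(count_cycles(tri, "cyclomatic"), 1L)
  tree <- flow_from_edges(7, cbind(c(1L, 1L, 2L, 2L), c(2L, 3L, 4L, 5L)))
  expect_equal(count_cycles(tree, "simple_directed"), 0L)
  expect_equal(count_cycles(tree, "cyclomatic"), 0L)
  set.seed(24)
  for (r in 1:30) {
    n <- sample(3:5, 1)
    ed <- random_digraph_edges(n, 0.4)
    if (nrow(ed) == 0) next
    fl <- flow_from_edges(n, ed)
    expect_equal(as.integer(count_cycles(fl, "simple_directed")),
                 bruteforce_cycle_count(n, ed))
  }
  # the enumeration cap returns a partial count with an overflow flag
  k6 <- expand.grid(from = 1:6, to = 1:6)
  k6 <- as.matrix(k6[k6$from != k6$to, ])
  capped <- count_cycles(flow_from_edges(6, k6), "simple_directed",
                         max_cycles = 10)
  expect_true(isTRUE(attr(capped, "overflow")))
  expect_equal(as.integer(capped), 10L)
  # uncapped: complete digraph K6 has sum over k of C(6,k) (k-1)! cycles
  full <- count_cycles(flow_from_edges(6, k6), "simple_directed")
  expect_equal(as.integer(full), bruteforce_cycle_count(6, k6))
})

test_that("cyclomatic number is |E| - |V| + components on the projection", {
  # two components: a triangle and a 2-path
  ed <- cbind(c(1L, 2L, 3L, 5L), c(2L, 3L, 1L, 6L))
  fl <- flow_from_edges(8, ed)
  expect_equal(count_cycles(fl, "cyclomatic"), 3L - 3L + 1L + (1L - 2L + 1L))
})

test_that("null models preserve degrees and reduce to input when edgeless", {
  empty <- flow_from_edges(5, matrix(integer(0), 0, 2))
  nm <- null_model_metrics(empty, reps = 3)
  expect_equal(nm$null_clustering, 0)
  expect_equal(nm$null_cycles, 0)
  set.seed(25)
  f <- generate_disaster_field("none")
  net <- rewire_network(ring_lattice(100, 4), 0.2)
  sim <- run_simulation(f, net)
  fl <- build_flow_network(sim$gifts, net$n, status = sim$alive)
  nm2 <- null_model_metrics(fl, reps = 5)
  expect_s3_class(nm2, "flow_metrics")
  expect_gte(nm2$null_clustering, 0)
  expect_gte(nm2$null_cycles, 0)
  expect_equal(nm2$clustering, clustering_coefficient(fl))
})

test_that("activated edges are a subset of the potential network", {
  set.seed(26)
  for (r in 1:10) {
    f <- generate_disaster_field(sample(osotua_scenarios(), 1), 4)
    net <- rewire_network(ring_lattice(100, 4), stats::runif(1))
    sim <- run_simulation(f, net)
    fl <- build_flow_network(sim$gifts, net$n, status = sim$alive)
    expect_true(flow_edges_in_potential(fl, net))
  }
})
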