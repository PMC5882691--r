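test_that("degree distribution is the per-degree node fraction", {
  expect_equal(degree_distribution(vg_star(5)),
               c(`1` = 0.8, `4` = 0.2))
  expect_equal(degree_distribution(vg_triangle()), c(`2` = 1))
  # isolated nodes land in P(0)
  g <- vg_from_edges(4, rbind(c(1, 2)))
  expect_equal(degree_distribution(g), c(`0` = 0.5, `1` = 0.5))
  # cumulative variant is the survival function
  expect_equal(degree_distribution(vg_star(5), cumulative = TRUE),
               c(`1` = 1, `4` = 0.2))
  expect_error(degree_distribution(igraph::make_empty_graph(0)),
               class = "vasculonet_invalid_input")
})

test_that("mean degree matches the handshake identity", {
  expect_equal(mean_degree(vg_path(3)), 4 / 3)
  expect_equal(mean_degree(vg_cycle(5)), 2)
  for (s in 1:20) {
    g <- random_vg(7, 0.4, seed = s)
    expect_equal(mean_degree(g), 2 * nrow(g$edges) / nrow(g$nodes))
  }
})

test_that("gamma index spans 0 (edgeless) to 1 (maximal planar)", {
  expect_equal(gamma_index(vg_from_edges(20, matrix(0, 0, 2))), 0)
  expect_equal(gamma_index(vg_triangle()), 1)
  mp <- maximal_planar_triangulation(10, seed = 3)
  expect_equal(nrow(mp$edges), 24)
  expect_equal(gamma_index(mp), 1)
  # gamma of any tree is (N-1)/(3(N-2)) exactly
  for (n in c(5, 9, 30)) {
    g <- generate_vascular_graph(n, "tree", seed = n)
    expect_equal(gamma_index(g), (n - 1) / (3 * (n - 2)))
  }
  expect_error(gamma_index(vg_from_edges(2, rbind(c(1, 2)))),
               class = "vasculonet_undefined_estimate")
  expect_warning(gamma_index(igraph::make_full_graph(5)), "planar")
})

test_that("average shortest path uses ordered pairs of the largest component", {
  expect_equal(avg_shortest_path(vg_path(3)), 4 / 3)
  expect_equal(avg_shortest_path(vg_triangle()), 1)
  # disconnected graph: only the largest component counts
  g <- vg_from_edges(5, rbind(c(1, 2), c(2, 3), c(4, 5)))
  expect_equal(avg_shortest_path(g), 4 / 3)
  expect_error(avg_shortest_path(vg_from_edges(3, matrix(0, 0, 2))),
               class = "vasculonet_undefined_estimate")
})

test_that("treeness is 1 on trees, 0 on cycles, hand value on mixtures", {
  g <- generate_vascular_graph(50, "tree", seed = 4)
  expect_equal(treeness(g), 1)
  expect_equal(treeness(vg_cycle(5)), 0)
  # triangle with a pendant 3-node path hanging off node 3:
  # pendant forest = path 3-4-5 (pairs at distance 1,1,2), whole-graph <L>
  # enumerated by the Floyd-Warshall oracle
  g2 <- vg_from_edges(5, rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5)))
  A <- adj_of(g2)
  expect_equal(treeness(g2), bf_treeness(A))
  expect_equal(bf_treeness(A), (1 + 1 + 2) / 3 / bf_avg_path_lc(A))
})

test_that("adding a chord to a tree strictly decreases treeness", {
  for (s in 1:5) {
    g <- generate_vascular_graph(30, "tree", seed = s)
    ig <- as_igraph(g)
    # add a chord between two non-adjacent leaves
    deg <- igraph::degree(ig)
    leaves <- which(deg == 1)
    ig2 <- ig + igraph::edges(as.character(c(leaves[1], leaves[2])))
    expect_lt(treeness(ig2), 1)
    expect_equal(treeness(ig), 1)
  }
})

test_that("clustering coefficient follows the local-triangle definition", {
  expect_equal(clustering_coefficient(vg_triangle()), 1)
  expect_equal(clustering_coefficient(vg_star(6)), 0)
})

test_that("assortativity is edge-end Pearson, -1 for stars, NA when regular", {
  expect_equal(as.numeric(assortativity(vg_star(5))), -1)
  r <- assortativity(vg_cycle(5))
  expect_true(is.na(r))
  expect_false(attr(r, "defined"))
  # agrees with igraph's implementation on irregular graphs
  for (s in 1:10) {
    g <- random_vg(10, 0.35, seed = 100 + s)
    ig <- as_igraph(g)
    if (igraph::ecount(ig) < 2 || sd(igraph::degree(ig)) == 0) next
    mine <- as.numeric(assortativity(g))
    ref <- igraph::assortativity_degree(ig)
    if (!is.nan(ref)) expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("largest component fraction covers connected and fragmented cases", {
  expect_equal(largest_component_fraction(vg_cycle(6)), 1)
  g <- vg_from_edges(10, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                               c(6, 7), c(7, 8), c(8, 9), c(9, 10)))
  expect_equal(largest_component_fraction(g), 0.5)
  expect_equal(largest_component_fraction(vg_from_edges(10, matrix(0, 0, 2))), 0.1)
})

test_that("KS comparison of degree samples behaves as a two-sample test", {
  same <- ks_compare_degrees(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  sep <- ks_compare_degrees(rep(1, 6), rep(4, 6))
  expect_true(sep$significant)
  a <- c(1, 1, 2, 3, 3, 4); b <- c(2, 2, 2, 3, 4, 4)
  expect_equal(ks_compare_degrees(a, b)$p_value,
               ks_compare_degrees(b, a)$p_value)
  expect_error(ks_compare_degrees(numeric(0), 1:3),
               class = "vasculonet_invalid_input")
})

test_that("all metrics match brute-force oracles on random small graphs", {
  for (s in 1:150) {
    n <- sample(3:7, 1)
    g <- random_vg(n, runif(1, 0.2, 0.8), seed = 2000 + s)
    A <- adj_of(g)
    expect_equal(mean_degree(g), bf_mean_degree(A))
    expect_equal(degree_distribution(g), bf_pk(A))
    expect_equal(suppressWarnings(gamma_index(g)), bf_gamma(A), tolerance = 1e-12)
    expect_equal(clustering_coefficient(g), bf_clustering(A), tolerance = 1e-12)
    expect_equal(largest_component_fraction(g), bf_lcc_fraction(A))
    if (max(tabulate(bf_components(A))) >= 2) {
      expect_equal(avg_shortest_path(g), bf_avg_path_lc(A), tolerance = 1e-12)
      expect_equal(treeness(g), bf_treeness(A), tolerance = 1e-12)
    }
    if (nrow(g$edges) >= 2) {
      expect_equal(as.numeric(assortativity(g)), bf_assortativity(A),
                   tolerance = 1e-12)
    }
  }
})

test_that("the metric suite is invariant under node relabelling", {
  g <- random_vg(9, 0.4, seed = 77)
  perm <- c(4, 9, 1, 7, 2, 8, 5, 3, 6)
  g2 <- vg_from_edges(9, cbind(perm[g$edges$from], perm[g$edges$to]))
  for (f in list(mean_degree, gamma_index, clustering_coefficient,
                 largest_component_fraction, treeness)) {
    expect_equal(f(g), f(g2))
  }
  expect_equal(sort(node_degrees(g)), sort(node_degrees(g2)))
})

test_that("network_metrics assembles the per-frame record", {
  g <- generate_vascular_graph(40, "lattice", seed = 9)
  m <- network_metrics(g, t_h = 2.5)
  expect_equal(m$n_nodes, 40)
  expect_equal(m$mean_degree, mean_degree(g))
  expect_equal(m$p1 + m$p2 + m$p3 + m$p4, 1)  # degrees 1..4 only
  expect_equal(m$t_h, 2.5)
})
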