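named_graph <- function(el, n = max(el)) {
  g <- igraph::make_graph(t(el), n = n, directed = FALSE)
  igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", seq_len(n)))
}

test_that("clustering coefficient on canonical graphs", {
  tri <- named_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
  cl <- clustering(tri)
  expect_equal(unname(cl$local), rep(1, 3))
  expect_equal(cl$average, 1)
  path3 <- named_graph(rbind(c(1, 2), c(2, 3)))
  expect_equal(unname(clustering(path3)$local), rep(0, 3))
  expect_equal(clustering(path3)$average, 0)  # only the middle node has k >= 2
  expect_equal(clustering(path3, include_low_degree = TRUE)$average, 0)
})

test_that("global metrics on a 3-node path match hand enumeration", {
  p3 <- named_graph(rbind(c(1, 2), c(2, 3)))
  g <- global_metrics(p3)
  expect_equal(g$characteristic_path_length, 4 / 3, tolerance = 1e-12)
  expect_equal(g$network_diameter, 2)
  expect_equal(g$shortest_paths, 6)  # ordered connected pairs
  expect_equal(g$network_density, 2 / 3, tolerance = 1e-12)
  expect_equal(g$connected_components, 1)
  expect_equal(g$average_degree, 4 / 3, tolerance = 1e-12)
})

test_that("star and regular graphs hit the centralization/heterogeneity limits", {
  star <- igraph::set_vertex_attr(igraph::make_star(9, "undirected"),
                                  "name", value = letters[1:9])
  g <- global_metrics(star)
  expect_equal(g$network_centralization, 1, tolerance = 1e-12)
  ring <- igraph::set_vertex_attr(igraph::make_ring(8), "name",
                                  value = letters[1:8])
  expect_equal(global_metrics(ring)$network_heterogeneity, 0)
  expect_true(is.na(global_metrics(ring)$degree_correlation))  # constant degree
  full <- igraph::set_vertex_attr(igraph::make_full_graph(5), "name",
                                  value = letters[1:5])
  expect_equal(global_metrics(full)$network_density, 1)
  expect_equal(global_metrics(full)$network_diameter, 1)
  # N < 3: centralization undefined, reported missing
  pair <- named_graph(rbind(c(1, 2)))
  expect_true(is.na(global_metrics(pair)$network_centralization))
})

test_that("centralities on canonical graphs match geodesic counts", {
  p3 <- named_graph(rbind(c(1, 2), c(2, 3)))
  nc <- node_centralities(p3)
  expect_equal(nc$betweenness, c(0, 1, 0))  # normalized by (N-1)(N-2)/2 = 1
  expect_equal(nc$stress, c(0, 1, 0))       # the single a-c geodesic
  star <- igraph::set_vertex_attr(igraph::make_star(6, "undirected"),
                                  "name", value = letters[1:6])
  nc2 <- node_centralities(star)
  expect_equal(nc2$eccentricity, c(1, rep(2, 5)))
  expect_equal(nc2$closeness[1], 1)
  expect_equal(nc2$stress[1], choose(5, 2))
})

test_that("all topology metrics match brute-force oracles on random graphs", {
  for (i in 1:10) {
    n <- sample(6:25, 1)
    g <- random_test_graph(n, runif(1, 0.1, 0.4), seed = 100 + i)
    A <- adjacency_of(g)
    gm <- global_metrics(g)
    orc <- oracle_centralities(A)
    D <- orc$distances
    finite <- is.finite(D) & D > 0
    expect_equal(unname(clustering(g)$local), oracle_clustering_local(A),
                 tolerance = 1e-12)
    expect_equal(gm$connected_components, orc$components)
    expect_equal(gm$shortest_paths, sum(finite))
    if (any(finite)) {
      expect_equal(gm$network_diameter, max(D[finite]))
      expect_equal(gm$characteristic_path_length, mean(D[finite]),
                   tolerance = 1e-12)
    }
    mu <- oracle_assortativity(A)
    if (is.na(mu)) expect_true(is.na(gm$degree_correlation))
    else expect_equal(gm$degree_correlation, mu, tolerance = 1e-9)
    nc <- node_centralities(g)
    expect_equal(nc$betweenness, orc$betweenness, tolerance = 1e-9)
    expect_equal(nc$stress, orc$stress)
    expect_equal(nc$closeness, orc$closeness, tolerance = 1e-12)
    expect_equal(nc$eccentricity, orc$eccentricity)
    expect_equal(nc$topological_coefficient,
                 oracle_topological_coefficient(A), tolerance = 1e-12)
  }
})

test_that("degree identities hold on random graphs", {
  for (i in 1:5) {
    g <- random_test_graph(sample(5:30, 1), runif(1, 0.1, 0.5), seed = 40 + i)
    gm <- global_metrics(g)
    n <- igraph::vcount(g)
    expect_equal(gm$network_density, gm$average_degree / (n - 1),
                 tolerance = 1e-12)
    expect_equal(sum(igraph::degree(g)), 2 * igraph::ecount(g))
  }
})

test_that("metrics are invariant under node relabeling", {
  g <- random_test_graph(15, 0.3, seed = 77)
  perm <- sepnet_with_seed(78, sample(15))
  g2 <- igraph::permute(g, perm)
  r1 <- topology_report(g)
  r2 <- topology_report(g2)
  expect_equal(unclass(r1), unclass(r2), tolerance = 1e-12)
  n1 <- node_centralities(g)
  n2 <- node_centralities(g2)
  n2 <- n2[match(n1$gene, n2$gene), ]
  expect_equal(n1$betweenness, n2$betweenness, tolerance = 1e-12)
  expect_equal(n1$stress, n2$stress)
})

test_that("community detection reproduces worked modularity values", {
  twotri <- named_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                              c(4, 5), c(5, 6), c(4, 6)))
  cl <- find_communities(twotri)
  expect_equal(cl$modularity, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(cl$membership)), 2)
  A <- adjacency_of(twotri)
  expect_equal(cl$modularity, oracle_modularity_q(A, cl$membership),
               tolerance = 1e-12)
  # a clique treated as one community has Q = 0
  k5 <- igraph::set_vertex_attr(igraph::make_full_graph(5), "name",
                                value = letters[1:5])
  expect_equal(modularity_q(k5, rep(1, 5)), 0, tolerance = 1e-12)
  expect_error(find_communities(named_graph(matrix(0, 0, 2), n = 3)),
               "edgeless")
})

test_that("greedy Q is never below the trivial one-community partition", {
  for (i in 1:5) {
    g <- random_test_graph(20, 0.2, seed = 300 + i)
    if (igraph::ecount(g) == 0) next
    q <- find_communities(g)$modularity
    expect_gte(q, modularity_q(g, rep(1, igraph::vcount(g))) - 1e-12)
  }
})

test_that("find_hubs ranks by degree with lexicographic ties", {
  star <- igraph::set_vertex_attr(igraph::make_star(7, "undirected"),
                                  "name", value = c("hub", letters[1:6]))
  expect_identical(find_hubs(star)$gene, "hub")
  # two tied maxima returned in lexicographic order at k = 2
  g <- named_graph(rbind(c(1, 2), c(1, 3), c(4, 2), c(4, 3)))
  h <- find_hubs(g, top_k = 2)
  expect_identical(h$gene, c("n01", "n02"))
  expect_equal(h$degree, c(2, 2))
  expect_error(find_hubs(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
})

test_that("topology_table uses the standard display names", {
  g <- random_test_graph(10, 0.3, seed = 9)
  tab <- topology_table(topology_report(g))
  expect_identical(tab$parameter[1], "Clustering coefficient")
  expect_identical(tab$parameter[nrow(tab)], "Modularity, Mc")
  expect_equal(nrow(tab), 12)
})
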