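# Topology metrics follow the NetworkAnalyzer conventions used to produce the
# reference tables: clustering coefficient averaged over nodes of degree >= 2,
# heterogeneity as the coefficient of variation of the degree distribution,
# path statistics over connected ordered node pairs only (disconnected pairs
# are excluded, never counted as infinite), betweenness normalized within each
# connected component, stress over unordered endpoint pairs.

# distance matrix, unweighted, Inf for disconnected pairs
dist_matrix_ <- function(net) {
  igraph::distances(net, weights = NA)
}

# geodesic (shortest-path) counts between all node pairs, by per-source DP
# over distance levels: sigma[s,t] = sum of sigma[s,u] over neighbors u of t
# at distance D[s,t] - 1.
geodesic_counts_ <- function(net, D = dist_matrix_(net)) {
  n <- igraph::vcount(net)
  adj <- igraph::as_adj_list(net)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    d <- D[s, ]
    reach <- which(is.finite(d) & d > 0)
    for (v in reach[order(d[reach])]) {
      nb <- as.integer(adj[[v]])
      pred <- nb[d[nb] == d[v] - 1]
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  dimnames(sigma) <- dimnames(D)
  sigma
}

#' Local and network clustering coefficients
#'
#' Per node, the fraction of its neighbor pairs that are themselves linked,
#' `C_n = 2 e_n / (k_n (k_n - 1))`; nodes with degree < 2 get 0. The network
#' value averages over nodes with degree >= 2 (set `include_low_degree = TRUE`
#' to average over all nodes, counting degree-<2 nodes as 0).
#'
#' @param net an igraph network.
#' @param include_low_degree include degree-<2 nodes in the network average.
#' @return list with `local` (named numeric per node) and `average`.
#' @export
clustering <- function(net, include_low_degree = FALSE) {
  k <- igraph::degree(net)
  loc <- igraph::transitivity(net, type = "local", isolates = "zero")
  loc[k < 2] <- 0
  names(loc) <- igraph::V(net)$name
  avg <- if (include_low_degree) {
    if (length(loc)) mean(loc) else NA_real_
  } else {
    if (any(k >= 2)) mean(loc[k >= 2]) else NA_real_
  }
  list(local = loc, average = avg)
}

#' Global topology metrics
#'
#' Computes the global parameter panel of a co-expression network: average
#' clustering coefficient, density `2E / (N (N - 1))`, heterogeneity
#' `sqrt(var(k)) / mean(k)` (population variance; coefficient of variation of
#' degree), connected component count, diameter and characteristic path length
#' over connected ordered pairs, the count of connected ordered pairs
#' (`shortest_paths`), average degree, node count, degree assortativity
#' (Pearson correlation of endpoint degrees over edges) and degree-based
#' centralization `(N / (N - 2)) (k_max / (N - 1) - density)` (undefined,
#' `NA`, for N < 3). Modularity is added by [topology_report()].
#'
#' @param net an igraph network with >= 2 nodes.
#' @param include_low_degree passed to [clustering()].
#' @return a named list of class `topology_report` (without `modularity`).
#' @export
global_metrics <- function(net, include_low_degree = FALSE) {
  n <- as.integer(igraph::vcount(net))
  if (n < 2L) abort_fmt("need >= 2 nodes")
  e <- igraph::ecount(net)
  k <- igraph::degree(net)
  density <- 2 * e / (n * (n - 1))
  kbar <- mean(k)
  het <- if (kbar > 0) sqrt(mean((k - kbar)^2)) / kbar else NA_real_
  D <- dist_matrix_(net)
  finite <- is.finite(D) & D > 0
  npairs <- sum(finite)
  diam <- if (npairs > 0) max(D[finite]) else NA_real_
  cpl <- if (npairs > 0) mean(D[finite]) else NA_real_
  centr <- if (n < 3L) NA_real_ else (n / (n - 2)) * (max(k) / (n - 1) - density)
  mu <- suppressWarnings(igraph::assortativity_degree(net, directed = FALSE))
  if (!is.finite(mu)) mu <- NA_real_
  structure(list(
    clustering_coefficient = clustering(net, include_low_degree)$average,
    network_density = density,
    network_heterogeneity = het,
    connected_components = igraph::components(net)$no,
    network_diameter = diam,
    network_centralization = centr,
    shortest_paths = npairs,
    characteristic_path_length = cpl,
    average_degree = kbar,
    n_nodes = n,
    degree_correlation = mu
  ), class = "topology_report")
}

#' Per-node centrality metrics
#'
#' Degree, local clustering coefficient, betweenness (shortest-path counting,
#' normalized by `(Nc - 1)(Nc - 2) / 2` within each connected component of
#' size `Nc`), closeness (`1 / mean distance` to reachable nodes; 0 for
#' isolated nodes), stress (raw count of geodesics passing through the node,
#' over unordered endpoint pairs), eccentricity (maximum distance within the
#' node's component) and the topological coefficient (average, over nodes
#' sharing at least one neighbor, of shared-neighbor counts plus the
#' adjacency indicator, divided by the node's degree; 0 for degree-<2 nodes).
#'
#' @param net an igraph network.
#' @return data.frame: `gene`, `degree`, `clustering`, `betweenness`,
#'   `closeness`, `stress`, `eccentricity`, `topological_coefficient`.
#' @export
node_centralities <- function(net) {
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  k <- igraph::degree(net)
  D <- dist_matrix_(net)
  comp <- igraph::components(net)

  btw <- igraph::betweenness(net, weights = NA, directed = FALSE)
  csize <- comp$csize[comp$membership]
  norm <- (csize - 1) * (csize - 2) / 2
  btw_norm <- ifelse(norm > 0, btw / norm, 0)

  closeness <- eccentricity <- numeric(n)
  for (v in seq_len(n)) {
    d <- D[v, ]
    reach <- is.finite(d) & d > 0
    closeness[v] <- if (any(reach)) 1 / mean(d[reach]) else 0
    eccentricity[v] <- if (any(reach)) max(d[reach]) else 0
  }

  # stress: sum over unordered connected pairs (s, t), both != v, of the
  # number of s-t geodesics passing through v
  sigma <- geodesic_counts_(net, D)
  finite <- is.finite(D) & D > 0
  stress <- numeric(n)
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], `+`) == D &
      finite & is.finite(D[, v]) & is.finite(D[v, ])
    contrib <- outer(sigma[, v], sigma[v, ]) * through
    contrib[v, ] <- 0
    contrib[, v] <- 0
    stress[v] <- sum(contrib[upper.tri(contrib)])
  }

  # topological coefficient
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  SH <- A %*% A
  topo <- numeric(n)
  for (v in seq_len(n)) {
    if (k[v] < 2) next
    cand <- which(SH[v, ] > 0)
    cand <- setdiff(cand, v)
    if (!length(cand)) next
    topo[v] <- mean((SH[v, cand] + A[v, cand]) / k[v])
  }

  data.frame(gene = nm, degree = k, clustering = clustering(net)$local,
             betweenness = btw_norm, closeness = closeness, stress = stress,
             eccentricity = eccentricity, topological_coefficient = topo,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Community detection and modularity
#'
#' Greedy agglomerative modularity maximization (Clauset-Newman-Moore, via
#' [igraph::cluster_fast_greedy()]; deterministic) and the Newman-Girvan
#' modularity Q of the resulting partition.
#'
#' @param net an igraph network with >= 1 edge.
#' @param seed integer seed; the default algorithm is deterministic but the
#'   seed is fixed anyway so any backend randomization stays reproducible.
#' @return list with `membership` (named integer vector) and `modularity`
#'   (the Q of the partition).
#' @export
find_communities <- function(net, seed = 1L) {
  if (igraph::ecount(net) == 0L) abort_fmt("cannot partition an edgeless graph")
  cl <- with_seed(seed, igraph::cluster_fast_greedy(
    igraph::simplify(net), weights = NULL))
  memb <- igraph::membership(cl)
  q <- igraph::modularity(igraph::simplify(net), memb)
  list(membership = stats::setNames(as.integer(memb), igraph::V(net)$name),
       modularity = q)
}

#' Modularity Q of a given partition
#'
#' @param net an igraph network.
#' @param membership integer community label per node.
#' @return Newman-Girvan Q.
#' @export
modularity_q <- function(net, membership) {
  igraph::modularity(net, membership)
}

#' Full topology report, including modularity
#'
#' @param net an igraph network.
#' @param seed passed to [find_communities()].
#' @param include_low_degree passed to [clustering()].
#' @return a `topology_report` list with the 12 global parameters.
#' @export
topology_report <- function(net, seed = 1L, include_low_degree = FALSE) {
  rep <- global_metrics(net, include_low_degree)
  rep$modularity <- if (igraph::ecount(net) > 0L) {
    find_communities(net, seed)$modularity
  } else {
    NA_real_
  }
  rep
}

#' @export
print.topology_report <- function(x, ...) {
  df <- topology_table(x)
  cat("<topology_report>\n")
  print(df, row.names = FALSE)
  invisible(x)
}

# display names used in the exported report tables
topology_display_names <- function() {
  c(clustering_coefficient = "Clustering coefficient",
    network_density = "Network density",
    network_heterogeneity = "Network heterogeneity",
    connected_components = "Connected components",
    network_diameter = "Network diameter",
    network_centralization = "Network centralization",
    shortest_paths = "Shortest path",
    characteristic_path_length = "Characteristic path length",
    average_degree = "Average degree, <k>",
    n_nodes = "Number of nodes, N",
    degree_correlation = "Degree correlation, mu",
    modularity = "Modularity, Mc")
}

#' Tabulate a topology report
#'
#' @param report a `topology_report`.
#' @return data.frame with columns `parameter` (display name) and `value`.
#' @export
topology_table <- function(report) {
  nm <- topology_display_names()
  nm <- nm[names(nm) %in% names(report)]
  data.frame(parameter = unname(nm),
             value = vapply(names(nm), function(f)
               as.numeric(report[[f]] %||% NA_real_), numeric(1L)),
             stringsAsFactors = FALSE)
}

#' Rank hub genes by degree
#'
#' @param net a nonempty igraph network.
#' @param top_k how many nodes to return.
#' @return data.frame `gene`, `degree`, sorted by degree descending with ties
#'   broken by gene ID.
#' @export
find_hubs <- function(net, top_k = 1L) {
  if (igraph::vcount(net) == 0L) abort_fmt("empty network")
  k <- igraph::degree(net)
  nm <- igraph::V(net)$name
  ord <- order(-k, nm)
  take <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(gene = nm[take], degree = unname(k[take]),
             row.names = NULL, stringsAsFactors = FALSE)
}
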