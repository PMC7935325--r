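# Brute-force oracles, independent of the package implementation: distances
# by Floyd-Warshall, triangles by exhaustive enumeration, centralities by
# explicit enumeration of every geodesic. Intended for graphs with <= ~40
# nodes.

random_test_graph <- function(n, p, seed) {
  g <- sepnet_with_seed(seed, igraph::sample_gnp(n, p))
  igraph::set_vertex_attr(g, "name", value = sprintf("n%02d", seq_len(n)))
}

sepnet_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

adjacency_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# all-pairs shortest paths, Floyd-Warshall
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# local clustering by exhaustive triangle counting
oracle_clustering_local <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, numeric(1))
}

# enumerate every geodesic between two nodes as vectors of node indices
oracle_all_geodesics <- function(A, D, s, t) {
  if (!is.finite(D[s, t]) || s == t) return(list())
  recurse <- function(t) {
    if (t == s) return(list(s))
    preds <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
    out <- list()
    for (u in preds) {
      for (path in recurse(u)) out <- c(out, list(c(path, t)))
    }
    out
  }
  recurse(t)
}

# betweenness (normalized per component), stress, closeness, eccentricity
# by explicit geodesic enumeration
oracle_centralities <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  btw_raw <- numeric(n)
  stress <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(D[s, t]) || D[s, t] == 0) next
      paths <- oracle_all_geodesics(A, D, s, t)
      total <- length(paths)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        stress[idx] <- stress[idx] + as.integer(tab)
        btw_raw[idx] <- btw_raw[idx] + as.integer(tab) / total
      }
    }
  }
  # component sizes for normalization
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    comp[is.finite(D[v, ])] <- cid
  }
  csize <- as.integer(table(comp))[comp]
  norm <- (csize - 1) * (csize - 2) / 2
  btw <- ifelse(norm > 0, btw_raw / norm, 0)

  closeness <- eccentricity <- numeric(n)
  for (v in seq_len(n)) {
    d <- D[v, ]
    reach <- is.finite(d) & d > 0
    closeness[v] <- if (any(reach)) 1 / mean(d[reach]) else 0
    eccentricity[v] <- if (any(reach)) max(d[reach]) else 0
  }
  list(betweenness = btw, stress = stress, closeness = closeness,
       eccentricity = eccentricity, components = max(comp),
       distances = D)
}

oracle_topological_coefficient <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  vapply(seq_len(n), function(v) {
    if (k[v] < 2) return(0)
    vals <- c()
    for (m in seq_len(n)) {
      if (m == v) next
      shared <- sum(A[v, ] > 0 & A[m, ] > 0)
      if (shared == 0) next
      vals <- c(vals, (shared + (A[v, m] > 0)) / k[v])
    }
    if (length(vals)) mean(vals) else 0
  }, numeric(1))
}

# Newman-Girvan modularity of a given partition, from first principles
oracle_modularity_q <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(NA_real_)
  k <- rowSums(A)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    e_c <- sum(A[idx, idx]) / 2
    q <- q + e_c / m - (sum(k[idx]) / (2 * m))^2
  }
  q
}

oracle_assortativity <- function(A) {
  k <- rowSums(A)
  e <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(e) < 2) return(NA_real_)
  x <- c(k[e[, 1]], k[e[, 2]])
  y <- c(k[e[, 2]], k[e[, 1]])
  suppressWarnings(stats::cor(x, y))
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- n / seq_len(n) * p[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# exact hypergeometric upper tail P[X >= x] by combinatorial sum
oracle_hyper_tail <- function(x, N, K, n) {
  sum(vapply(x:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# small expression matrix builder
toy_matrix <- function(values, groups, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("s%02d", seq_len(ncol(values)))
  expr_matrix(values, group = groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
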