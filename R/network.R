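#' Spearman correlation matrix of an expression matrix
#'
#' Computes the gene x gene Spearman (midrank) correlation over the samples of
#' the chosen group, with two-sided p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (`rho = +/-1` receives `p = 0`). An exact small-sample option delegates to
#' [stats::cor.test()] per pair and is intended for `n < 10`.
#'
#' Genes with zero variance in the selected samples have no defined rank
#' correlation; their rows/columns are set to `NA` with a warning and never
#' produce edges.
#'
#' @param m an [expr_matrix()].
#' @param group sample subset passed to [select_group()].
#' @param genes optional character vector restricting the computation (e.g.
#'   the annotated immune gene set).
#' @param method `"t"` (default) or `"exact"`.
#' @return a `correlation_matrix`: list with `rho` and `p` (symmetric
#'   matrices, unit / zero diagonal) and `n` (sample count used).
#' @export
spearman_matrix <- function(m, group = "all", genes = NULL,
                            method = c("t", "exact")) {
  method <- match.arg(method)
  m <- select_group(m, group)
  if (!is.null(genes)) {
    keep <- intersect(gene_ids(m), genes)
    if (length(keep) < 2L) abort_fmt("fewer than 2 requested genes present")
    m$values <- m$values[keep, , drop = FALSE]
  }
  n <- n_samples(m)
  if (n < 4L) abort_fmt("need >= 4 samples for correlation (got %d)", n)

  constant <- apply(m$values, 1L, function(x) length(unique(x)) == 1L)
  if (any(constant)) {
    warn_fmt("%d zero-variance gene(s) excluded from correlations",
             sum(constant))
  }
  ranks <- t(apply(m$values, 1L, rank))  # midranks for ties
  rho <- suppressWarnings(stats::cor(t(ranks)))  # Pearson of ranks = Spearman
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- ifelse(constant, NA_real_, 1)

  if (method == "t") {
    r <- pmin(pmax(rho, -1), 1)
    tval <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    p <- 2 * stats::pt(-abs(tval), n - 2)
    p[abs(r) == 1] <- 0
  } else {
    ng <- nrow(rho)
    p <- matrix(NA_real_, ng, ng, dimnames = dimnames(rho))
    for (i in seq_len(ng - 1L)) {
      if (constant[i]) next
      for (j in seq((i + 1L), ng)) {
        if (constant[j]) next
        ct <- suppressWarnings(
          stats::cor.test(m$values[i, ], m$values[j, ],
                          method = "spearman", exact = TRUE))
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  diag(p) <- ifelse(constant, NA_real_, 0)
  structure(list(rho = rho, p = p, n = n), class = "correlation_matrix")
}

#' Build a co-expression network from a correlation matrix
#'
#' Genes are nodes and an undirected edge joins genes i and j iff
#' `rho_ij >= rho_min` and `p_ij < alpha` (with `absolute = TRUE` the rule is
#' `|rho_ij| >= rho_min`). Genes left without any edge are dropped from the
#' network; an edgeless result is returned (with a warning), not an error.
#'
#' @param cmat a `correlation_matrix` from [spearman_matrix()].
#' @param annotation optional named character vector gene -> category used to
#'   tag nodes (genes missing from it get `"U"`).
#' @param rho_min inclusive correlation threshold in `(0, 1]`.
#' @param alpha edge p-value threshold.
#' @param absolute threshold `|rho|` instead of signed `rho`.
#' @return an [igraph::igraph] with vertex attributes `name` and `category`
#'   and edge attribute `rho`.
#' @export
build_network <- function(cmat, annotation = NULL, rho_min = 0.8,
                          alpha = 0.05, absolute = FALSE) {
  stopifnot(inherits(cmat, "correlation_matrix"))
  if (rho_min <= 0 || rho_min > 1) abort_fmt("rho_min must be in (0, 1]")
  if (alpha <= 0 || alpha > 1) abort_fmt("alpha must be in (0, 1]")
  r <- cmat$rho
  score <- if (absolute) abs(r) else r
  keep <- !is.na(score) & score >= rho_min & !is.na(cmat$p) & cmat$p < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warn_fmt("no edge passes rho >= %.2f, p < %.3g: returning empty network",
             rho_min, alpha)
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = character(0))
    g <- igraph::set_vertex_attr(g, "category", value = character(0))
    return(g)
  }
  genes <- rownames(r)
  edges <- data.frame(from = genes[idx[, 1L]], to = genes[idx[, 2L]],
                      rho = r[keep], stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  cat_of <- function(g) {
    if (is.null(annotation)) "U"
    else if (g %in% names(annotation)) unname(annotation[[g]])
    else "U"
  }
  vdf <- data.frame(name = nodes,
                    category = vapply(nodes, cat_of, character(1L)),
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vdf)
}

#' Export a co-expression network
#'
#' Writes GraphML (node categories and edge correlations as attributes) or an
#' edge-table TSV (`gene_a`, `gene_b`, `rho`) with a companion node TSV
#' (`gene`, `category`, `degree`).
#'
#' @param net an igraph network from [build_network()].
#' @param path output path; for `format = "tsv"` the node table is written
#'   next to it with suffix `_nodes.tsv`.
#' @param format `"graphml"` or `"tsv"`.
#' @return invisibly, the path(s) written.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_data_frame(net, what = "edges")
  edges <- data.frame(gene_a = el$from, gene_b = el$to,
                      rho = if ("rho" %in% names(el)) el$rho
                            else rep(NA_real_, nrow(el)),
                      stringsAsFactors = FALSE)
  write_tsv_(edges, path)
  nodes <- data.frame(gene = igraph::V(net)$name,
                      category = igraph::V(net)$category,
                      degree = igraph::degree(net),
                      stringsAsFactors = FALSE)
  npath <- sub("\\.tsv$", "_nodes.tsv", path)
  if (npath == path) npath <- paste0(path, "_nodes.tsv")
  write_tsv_(nodes, npath)
  invisible(c(path, npath))
}

#' Re-import a network written by [export_network()]
#'
#' @param path a GraphML file.
#' @return an igraph network with the original vertex/edge attributes.
#' @export
import_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
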