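#' Percent difference between a case and a control parameter value
#'
#' `(case - control) / control * 100`, the convention used to compare network
#' parameters between conditions. Undefined when `control == 0` (`NA` with a
#' warning). Full precision is returned; display rounding (one decimal,
#' round-half-even) is left to report formatting.
#'
#' @param case,control numeric values (vectorized).
#' @return percent difference(s).
#' @export
#' @examples
#' percent_difference(0.337, 0.390)  # clustering coefficient, about -13.6
percent_difference <- function(case, control) {
  out <- ifelse(control == 0, NA_real_, (case - control) / control * 100)
  if (anyNA(out) & any(control == 0, na.rm = TRUE)) {
    warn_fmt("control value 0: percent difference undefined, reported as NA")
  }
  out
}

#' Compare two topology reports parameter by parameter
#'
#' @param control,case `topology_report`s over the same parameter set.
#' @return data.frame: `parameter` (display name), `control`, `case`,
#'   `pct_difference` (full precision), `pct_display` (rounded to one
#'   decimal), `direction` (`"increased"` / `"decreased"` / `"unchanged"` in
#'   case relative to control, `NA` when undefined).
#' @export
compare_reports <- function(control, case) {
  if (!setequal(names(control), names(case))) {
    abort_fmt("reports have mismatched parameter sets")
  }
  nm <- topology_display_names()
  nm <- nm[names(nm) %in% names(control)]
  ctrl_v <- vapply(names(nm), function(f)
    as.numeric(control[[f]] %||% NA_real_), numeric(1L))
  case_v <- vapply(names(nm), function(f)
    as.numeric(case[[f]] %||% NA_real_), numeric(1L))
  pd <- suppressWarnings(percent_difference(case_v, ctrl_v))
  pd[is.na(ctrl_v) | is.na(case_v)] <- NA_real_
  dir <- ifelse(is.na(pd), NA_character_,
                ifelse(pd > 0, "increased",
                       ifelse(pd < 0, "decreased", "unchanged")))
  data.frame(parameter = unname(nm), control = ctrl_v, case = case_v,
             pct_difference = pd, pct_display = round(pd, 1L),
             direction = dir, row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect prominent, category-enriched clusters in a network
#'
#' Operationalizes "prominent and isolated functional cluster": every
#' connected component with at least `min_size` nodes is scored for its
#' dominant functional category with a one-sided hypergeometric enrichment
#' test. The background category frequencies are taken over all genes covered
#' by `annotation` (the annotated universe handed to the network builder), so
#' a component keeps its enrichment even when the rest of the graph is empty.
#' Components other than the largest are flagged `is_isolated`.
#'
#' @param net an igraph network with vertex attribute `category` (used for
#'   nodes missing from `annotation`).
#' @param annotation named character vector gene -> category defining the
#'   background frequencies; defaults to the network's own node categories.
#' @param min_size minimum component size to score.
#' @param alpha enrichment p-value threshold for the `significant` flag.
#' @return data.frame sorted by enrichment p: `component` (id), `size`,
#'   `dominant_category`, `dominant_count`, `dominant_fraction`, `p_enrich`,
#'   `significant`, `is_isolated`, `genes` (comma-joined). Zero rows when no
#'   component reaches `min_size`.
#' @export
detect_isolated_clusters <- function(net, annotation = NULL, min_size = 5L,
                                     alpha = 0.05) {
  empty <- data.frame(component = integer(0), size = integer(0),
                      dominant_category = character(0),
                      dominant_count = integer(0),
                      dominant_fraction = numeric(0),
                      p_enrich = numeric(0), significant = logical(0),
                      is_isolated = logical(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (igraph::vcount(net) == 0L) return(empty)
  nodecat <- stats::setNames(igraph::V(net)$category, igraph::V(net)$name)
  if (is.null(annotation)) annotation <- nodecat
  bg <- table(as.character(annotation))
  N <- sum(bg)
  comp <- igraph::components(net)
  largest <- which.max(comp$csize)
  rows <- lapply(which(comp$csize >= min_size), function(ci) {
    members <- names(comp$membership)[comp$membership == ci]
    cats <- ifelse(members %in% names(annotation),
                   as.character(annotation[members]),
                   as.character(nodecat[members]))
    tab <- sort(table(cats), decreasing = TRUE)
    dom <- names(tab)[1L]
    x <- as.integer(tab[1L])
    K <- if (dom %in% names(bg)) as.integer(bg[[dom]]) else x
    n <- length(members)
    # P[X >= x], X ~ Hypergeom(N, K, n)
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(component = ci, size = n, dominant_category = dom,
               dominant_count = x, dominant_fraction = x / n,
               p_enrich = p, significant = p < alpha,
               is_isolated = ci != largest,
               genes = paste(sort(members), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$p_enrich, out$component), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus of cluster findings and enrichment calls across datasets
#'
#' @param cluster_genes named list (one element per dataset) of character
#'   vectors: the genes found in the clusters of interest of each dataset.
#' @param enrichment_tables optional named list of [gage_enrichment()] results
#'   per dataset, used to tally how many datasets flag each pathway/direction
#'   significant (the "5/6 datasets" style counts).
#' @return list with `genes` (data.frame `gene`, `k`, `n`, `k_of_n`,
#'   `in_all`), `intersection` (genes present in every dataset) and, when
#'   enrichment tables are given, `pathways` (data.frame `pathway`,
#'   `direction`, `k`, `n`, `k_of_n`).
#' @export
cross_dataset_consensus <- function(cluster_genes, enrichment_tables = NULL) {
  if (length(cluster_genes) < 2L) abort_fmt("need >= 2 datasets")
  n <- length(cluster_genes)
  tal <- table(unlist(lapply(cluster_genes, unique)))
  genes <- data.frame(gene = names(tal), k = as.integer(tal), n = n,
                      k_of_n = sprintf("%d/%d", as.integer(tal), n),
                      in_all = as.integer(tal) == n,
                      stringsAsFactors = FALSE)
  genes <- genes[order(-genes$k, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  out <- list(genes = genes,
              intersection = sort(genes$gene[genes$in_all]))
  if (!is.null(enrichment_tables)) {
    nn <- length(enrichment_tables)
    sig <- lapply(enrichment_tables, function(tb) {
      tb <- tb[tb$significant, c("pathway", "direction"), drop = FALSE]
      unique(tb)
    })
    all_sig <- do.call(rbind, sig)
    if (is.null(all_sig) || nrow(all_sig) == 0L) {
      out$pathways <- data.frame(pathway = character(0),
                                 direction = character(0), k = integer(0),
                                 n = integer(0), k_of_n = character(0),
                                 stringsAsFactors = FALSE)
    } else {
      key <- paste(all_sig$pathway, all_sig$direction, sep = "\r")
      tal <- table(key)
      parts <- strsplit(names(tal), "\r", fixed = TRUE)
      out$pathways <- data.frame(
        pathway = vapply(parts, `[[`, "", 1L),
        direction = vapply(parts, `[[`, "", 2L),
        k = as.integer(tal), n = nn,
        k_of_n = sprintf("%d/%d", as.integer(tal), nn),
        stringsAsFactors = FALSE)
      out$pathways <- out$pathways[order(-out$pathways$k,
                                         out$pathways$pathway), , drop = FALSE]
      rownames(out$pathways) <- NULL
    }
  }
  out
}
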