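#' Assemble and validate a pipeline configuration
#'
#' One object holds every threshold the analysis uses, the seed, and either a
#' synthetic-data specification or paths to an expression/metadata TSV pair.
#'
#' @param synthetic a [synthetic_config()], or `NULL` when reading from files.
#' @param expression_path,metadata_path input TSVs (ignored in synthetic
#'   mode).
#' @param log2,quantile apply [log2_transform()] / [quantile_normalize()]
#'   during ingestion.
#' @param balance apply [balanced_subsample()] so both groups have the control
#'   group's size (never applied in synthetic mode, whose groups are already
#'   balanced by construction).
#' @param rho_min,edge_alpha network thresholds (see [build_network()]).
#' @param absolute threshold on `|rho|` instead of signed rho.
#' @param fdr FDR threshold for differential expression.
#' @param gsea_alpha global p-value threshold for enrichment.
#' @param min_cluster_size minimum component size for cluster findings.
#' @param groups which sample subsets get their own network; any of
#'   `"control"`, `"case"`, `"survivor"`, `"nonsurvivor"`. The first two
#'   entries are compared in the percent-difference report (first = control
#'   side).
#' @param registry a `pathway_registry` used for annotation and enrichment; in
#'   synthetic mode the generator's category map and category gene sets are
#'   used instead.
#' @param seed integer seed for every stochastic step.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            expression_path = NULL, metadata_path = NULL,
                            log2 = FALSE, quantile = FALSE, balance = FALSE,
                            rho_min = 0.8, edge_alpha = 0.05,
                            absolute = FALSE, fdr = 0.01, gsea_alpha = 0.05,
                            min_cluster_size = 5L,
                            groups = c("control", "case"),
                            registry = NULL, seed = 1L) {
  if (is.null(synthetic) &&
      (is.null(expression_path) || is.null(metadata_path))) {
    abort_fmt("either `synthetic` or both input paths must be given")
  }
  if (rho_min <= 0 || rho_min > 1) abort_fmt("rho_min must be in (0, 1]")
  for (nm in c("edge_alpha", "fdr", "gsea_alpha")) {
    v <- get(nm)
    if (v <= 0 || v > 1) abort_fmt("%s must be in (0, 1]", nm)
  }
  if (min_cluster_size < 2L) abort_fmt("min_cluster_size must be >= 2")
  bad <- setdiff(groups, c("control", "case", "survivor", "nonsurvivor"))
  if (length(bad)) abort_fmt("unknown groups: %s", paste(bad, collapse = ", "))
  if (length(groups) < 1L) abort_fmt("need at least one group")
  # one seed governs the whole run, including the synthetic generator
  if (!is.null(synthetic)) synthetic$seed <- as.integer(seed)
  structure(list(synthetic = synthetic, expression_path = expression_path,
                 metadata_path = metadata_path, log2 = log2,
                 quantile = quantile, balance = balance, rho_min = rho_min,
                 edge_alpha = edge_alpha, absolute = absolute, fdr = fdr,
                 gsea_alpha = gsea_alpha,
                 min_cluster_size = as.integer(min_cluster_size),
                 groups = groups, registry = registry,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; a `synthetic:`
#' block (keys of [synthetic_config()], with `blocks:` as a list of
#' `gene_from`/`gene_to`/`rho_in`/`active_group`/`category` entries and
#' `shift:` as `from`/`to`/`shift`) switches on synthetic mode.
#'
#' @param path YAML file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    blocks <- lapply(s$blocks %||% list(), function(b) {
      block_spec(seq(b$gene_from, b$gene_to), rho_in = b$rho_in,
                 active_group = b$active_group %||% "both",
                 category = b$category %||% "adaptive immunity")
    })
    shifts <- if (is.null(s$shift)) NULL else
      data.frame(index = seq(s$shift$from, s$shift$to),
                 shift = s$shift$shift)
    syn <- synthetic_config(
      n_genes = s$n_genes %||% 320L,
      n_control = s$n_control %||% 25L, n_case = s$n_case %||% 25L,
      blocks = blocks, shift_genes = shifts,
      noise_sd = s$noise_sd %||% 1, seed = y$seed %||% 1L)
  }
  pipeline_config(
    synthetic = syn,
    expression_path = y$expression_path, metadata_path = y$metadata_path,
    log2 = isTRUE(y$log2), quantile = isTRUE(y$quantile),
    balance = isTRUE(y$balance),
    rho_min = y$rho_min %||% 0.8, edge_alpha = y$edge_alpha %||% 0.05,
    absolute = isTRUE(y$absolute), fdr = y$fdr %||% 0.01,
    gsea_alpha = y$gsea_alpha %||% 0.05,
    min_cluster_size = y$min_cluster_size %||% 5L,
    groups = unlist(y$groups %||% c("control", "case")),
    seed = y$seed %||% 1L)
}

stage_msg_ <- function(stage, t0) {
  message(sprintf("[sepnet] %-12s %.2fs", stage,
                  as.numeric(proc.time()[["elapsed"]]) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data generation or ingestion (with optional log2 /
#' quantile normalization and balanced subsampling), gene annotation,
#' differential expression and gene set enrichment on the full matrix, one
#' co-expression network per requested group restricted to the annotated
#' genes, topology reports and per-node centralities, cluster findings, and
#' the percent-difference comparison between the first two groups. All files
#' are written under `out_dir`; a manifest records the package version, seed
#' and thresholds (no timestamps), so a rerun with identical config and seed
#' is bit-identical.
#'
#' @param config a `pipeline_config` (or path to a YAML file).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the result bundle: list with `matrix`, `annotation`,
#'   `deg`, `enrichment`, `directions`, per-group `networks`, `reports`,
#'   `centralities` and `findings`, `comparison`, `truth` (synthetic mode) and
#'   `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(proc.time()[["elapsed"]])
  paths <- character(0)
  wr <- function(nm, p) { paths[[nm]] <<- p; p }

  # --- data -----------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    ds <- generate_dataset(config$synthetic)
    m <- ds$matrix
    truth <- ds$truth
    p <- write_synthetic(ds, out_dir)
    paths <- c(paths, p)
  } else {
    m <- read_expression(config$expression_path, config$metadata_path)
    if (config$log2) m <- log2_transform(m)
    if (config$quantile) m <- quantile_normalize(m)
    if (config$balance) m <- balanced_subsample(m, seed = config$seed)
    write_expression(m, wr("expression", file.path(out_dir, "expression.tsv")),
                     wr("metadata", file.path(out_dir, "metadata.tsv")))
  }
  stage_msg_("data", t0)

  # --- annotation -----------------------------------------------------------
  if (!is.null(truth)) {
    annotation <- truth$category_map
    gene_sets <- split(names(annotation), annotation)
  } else {
    registry <- config$registry %||% default_registry()
    annotation <- annotate_all(registry)
    gene_sets <- registry$gene_sets
  }
  write_annotation(annotation, wr("annotation",
                                  file.path(out_dir, "annotation.tsv")))
  stage_msg_("annotation", t0)

  # --- differential expression + enrichment ---------------------------------
  deg <- welch_t(m, fdr_threshold = config$fdr)
  write_tsv_(deg, wr("deg", file.path(out_dir, "deg.tsv")))
  enrichment <- suppressWarnings(
    gage_enrichment(m, gene_sets, alpha = config$gsea_alpha))
  write_tsv_(enrichment, wr("enrichment",
                            file.path(out_dir, "enrichment.tsv")))
  directions <- summarize_directions(enrichment)
  stage_msg_("deg/gsea", t0)

  # --- per-group networks and topology --------------------------------------
  immune_genes <- intersect(gene_ids(m), names(annotation))
  networks <- reports <- centralities <- findings <- list()
  for (g in config$groups) {
    cm <- suppressWarnings(spearman_matrix(m, group = g,
                                           genes = immune_genes))
    net <- suppressWarnings(build_network(cm, annotation,
                                          rho_min = config$rho_min,
                                          alpha = config$edge_alpha,
                                          absolute = config$absolute))
    networks[[g]] <- net
    export_network(net, wr(paste0("network_", g),
                           file.path(out_dir,
                                     sprintf("network_%s.graphml", g))),
                   format = "graphml")
    export_network(net, file.path(out_dir, sprintf("edges_%s.tsv", g)),
                   format = "tsv")
    paths[[paste0("edges_", g)]] <- file.path(out_dir,
                                              sprintf("edges_%s.tsv", g))
    if (igraph::vcount(net) >= 2L) {
      reports[[g]] <- topology_report(net, seed = config$seed)
      centralities[[g]] <- node_centralities(net)
    } else {
      reports[[g]] <- NULL
      centralities[[g]] <- NULL
    }
    if (!is.null(reports[[g]])) {
      jsonlite::write_json(unclass(reports[[g]]),
                           wr(paste0("topology_", g),
                              file.path(out_dir,
                                        sprintf("topology_%s.json", g))),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_tsv_(centralities[[g]],
                 wr(paste0("nodes_", g),
                    file.path(out_dir, sprintf("node_metrics_%s.tsv", g))))
    }
    findings[[g]] <- detect_isolated_clusters(
      net, annotation, min_size = config$min_cluster_size,
      alpha = config$edge_alpha)
    write_tsv_(findings[[g]],
               wr(paste0("clusters_", g),
                  file.path(out_dir, sprintf("clusters_%s.tsv", g))))
    stage_msg_(paste0("network:", g), t0)
  }

  # --- comparison -----------------------------------------------------------
  comparison <- NULL
  g1 <- config$groups[1L]
  g2 <- if (length(config$groups) >= 2L) config$groups[2L] else NULL
  if (!is.null(g2) && !is.null(reports[[g1]]) && !is.null(reports[[g2]])) {
    comparison <- compare_reports(reports[[g1]], reports[[g2]])
    write_tsv_(comparison, wr("comparison",
                              file.path(out_dir, "comparison.tsv")))
  }

  manifest <- list(
    package = "sepnet",
    version = as.character(utils::packageVersion("sepnet")),
    seed = config$seed,
    thresholds = list(rho_min = config$rho_min,
                      edge_alpha = config$edge_alpha,
                      absolute = config$absolute, fdr = config$fdr,
                      gsea_alpha = config$gsea_alpha,
                      min_cluster_size = config$min_cluster_size),
    groups = config$groups,
    synthetic = !is.null(config$synthetic))
  jsonlite::write_json(manifest, wr("manifest",
                                    file.path(out_dir, "manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_msg_("done", t0)

  invisible(list(matrix = m, annotation = annotation, deg = deg,
                 enrichment = enrichment, directions = directions,
                 networks = networks, reports = reports,
                 centralities = centralities, findings = findings,
                 comparison = comparison, truth = truth, paths = paths))
}

#' Consensus report across several pipeline bundles
#'
#' Collects, per dataset, the genes of significant cluster findings of one
#' functional category in one group's network, plus the enrichment tables, and
#' tallies them with [cross_dataset_consensus()].
#'
#' @param bundles named list of [run_pipeline()] results.
#' @param category functional category whose clusters are collected.
#' @param group which group's findings to use.
#' @return see [cross_dataset_consensus()].
#' @export
consensus_from_bundles <- function(bundles, category = "adaptive immunity",
                                   group = "case") {
  cluster_genes <- lapply(bundles, function(b) {
    f <- b$findings[[group]]
    f <- f[f$significant & f$dominant_category == category, , drop = FALSE]
    unique(unlist(strsplit(f$genes, ",", fixed = TRUE)))
  })
  cross_dataset_consensus(cluster_genes,
                          lapply(bundles, function(b) b$enrichment))
}
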