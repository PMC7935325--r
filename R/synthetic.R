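#' Specify a planted correlation block
#'
#' A block is a set of genes that is equicorrelated (pairwise Pearson
#' `rho_in`) in the samples of its active group and independent elsewhere.
#' Equicorrelated Gaussian blocks are used because their covariance matrix is
#' positive semi-definite whenever `rho_in >= -1/(k-1)` and because the
#' implied population Spearman correlation has the closed form
#' `(6/pi) * asin(rho_in / 2)`, which makes calibration checks analytic.
#'
#' @param gene_indices integer indices (length >= 2) of the member genes.
#' @param rho_in within-block Pearson correlation, in `[0, 1)`.
#' @param rho_out correlation to non-members; only 0 is supported (members of
#'   different blocks and background genes are independent).
#' @param active_group `"control"`, `"case"` or `"both"`.
#' @param category functional category label planted on the member genes.
#' @return a `block_spec` list.
#' @export
block_spec <- function(gene_indices, rho_in, rho_out = 0,
                       active_group = c("both", "control", "case"),
                       category = "adaptive immunity") {
  active_group <- match.arg(active_group)
  gene_indices <- as.integer(gene_indices)
  if (length(gene_indices) < 2L) abort_fmt("a block needs >= 2 genes")
  if (anyDuplicated(gene_indices)) abort_fmt("duplicated gene index in block")
  k <- length(gene_indices)
  if (rho_in >= 1 || rho_in < -1 / (k - 1)) {
    abort_fmt(paste0("rho_in = %.3f gives a non-positive-semi-definite ",
                     "covariance for a %d-gene block (need -1/(k-1) <= ",
                     "rho_in < 1)"), rho_in, k)
  }
  if (rho_out != 0) abort_fmt("only rho_out = 0 is supported")
  structure(list(gene_indices = gene_indices, rho_in = rho_in,
                 rho_out = rho_out, active_group = active_group,
                 category = category),
            class = "block_spec")
}

#' Configure the synthetic expression generator
#'
#' Defaults emulate the balanced designs analyzed in the study: two equal
#' groups of 25 samples, 320 genes spread over the 10 immune functional
#' categories, one planted 20-gene block (within-block Pearson 0.9, active in
#' the case group only, category "adaptive immunity"), one 12-gene block
#' shared by both groups (Pearson 0.85, category "platelet activity", so the
#' control network is not empty), and case-group mean shifts (+2 SD) on the
#' case-only block genes so that differential expression and enrichment have
#' signal to recover. Values are emitted on a log2-like scale (baseline mean
#' 8, SD 1) so that normalization steps are meaningful.
#'
#' @param n_genes total number of genes.
#' @param n_control,n_case samples per group.
#' @param blocks list of [block_spec()]s with disjoint gene index sets.
#' @param shift_genes data.frame with columns `index` (gene index) and `shift`
#'   (case-group mean shift in SD units, signed), or `NULL` for none.
#' @param noise_sd positive residual SD (the per-gene SD of the log2 values).
#' @param baseline_mean mean log2 intensity of every gene.
#' @param category_map optional character vector of length `n_genes` mapping
#'   gene index -> category; by default the 10 immune categories are assigned
#'   round-robin and then overwritten by each block's category on its members.
#' @param seed integer seed; all randomness flows through one generator
#'   instance keyed by it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 320L,
                             n_control = 25L,
                             n_case = 25L,
                             blocks = list(
                               block_spec(1:20, rho_in = 0.9,
                                          active_group = "case",
                                          category = "adaptive immunity"),
                               block_spec(21:32, rho_in = 0.85,
                                          active_group = "both",
                                          category = "platelet activity")
                             ),
                             shift_genes = data.frame(index = 1:20,
                                                      shift = 2),
                             noise_sd = 1,
                             baseline_mean = 8,
                             category_map = NULL,
                             seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_control <- as.integer(n_control)
  n_case <- as.integer(n_case)
  if (n_genes < 1L || n_control < 1L || n_case < 1L) {
    abort_fmt("n_genes, n_control and n_case must be positive")
  }
  if (noise_sd <= 0) abort_fmt("noise_sd must be > 0")
  if (!is.list(blocks)) abort_fmt("`blocks` must be a list of block_spec")
  idx <- unlist(lapply(blocks, function(b) b$gene_indices))
  if (anyDuplicated(idx)) abort_fmt("block gene index sets must be disjoint")
  if (length(idx) && (min(idx) < 1L || max(idx) > n_genes)) {
    abort_fmt("block gene index out of range 1..%d", n_genes)
  }
  if (!is.null(shift_genes)) {
    if (!all(c("index", "shift") %in% names(shift_genes))) {
      abort_fmt("shift_genes needs columns `index` and `shift`")
    }
    if (any(shift_genes$index < 1L | shift_genes$index > n_genes)) {
      abort_fmt("shift gene index out of range 1..%d", n_genes)
    }
  }
  if (is.null(category_map)) {
    category_map <- rep_len(immune_categories(), n_genes)
    for (b in blocks) category_map[b$gene_indices] <- b$category
  } else if (length(category_map) != n_genes) {
    abort_fmt("category_map must have one label per gene")
  }
  structure(list(n_genes = n_genes, n_control = n_control, n_case = n_case,
                 blocks = blocks, shift_genes = shift_genes,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 category_map = category_map, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic grouped expression dataset
#'
#' Draws gene expression for `n_control + n_case` samples: genes inside a
#' block active in a sample's group follow an equicorrelated multivariate
#' normal (correlation `rho_in`, built as `sqrt(rho) * shared factor +
#' sqrt(1 - rho) * idiosyncratic`), all other genes are independent normal
#' noise; `shift_genes` move the case-group mean by `shift * noise_sd`.
#' Identical seeds give bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `matrix` (an [expr_matrix()], gene IDs
#'   `g0001`... and sample IDs `ctrl_01`... / `case_01`...), and `truth` (a
#'   `synthetic_truth` list recording block memberships and categories, the
#'   differentially expressed gene IDs, and per-group target correlations).
#' @export
#' @examples
#' d <- generate_dataset(synthetic_config(n_genes = 50, seed = 7,
#'                                        blocks = list(block_spec(1:5, 0.9))))
#' d$matrix
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ng <- config$n_genes
  ns <- config$n_control + config$n_case
  group <- rep(c("control", "case"), c(config$n_control, config$n_case))
  gids <- sprintf("g%04d", seq_len(ng))
  sids <- c(sprintf("ctrl_%02d", seq_len(config$n_control)),
            sprintf("case_%02d", seq_len(config$n_case)))

  vals <- with_seed(config$seed, {
    z <- matrix(stats::rnorm(ng * ns), ng, ns)
    for (b in config$blocks) {
      active <- if (b$active_group == "both") rep(TRUE, ns)
                else group == b$active_group
      if (!any(active) || b$rho_in == 0) next
      shared <- stats::rnorm(sum(active))
      z[b$gene_indices, active] <-
        sqrt(b$rho_in) * matrix(shared, length(b$gene_indices),
                                sum(active), byrow = TRUE) +
        sqrt(1 - b$rho_in) * z[b$gene_indices, active]
    }
    z
  })
  vals <- config$baseline_mean + config$noise_sd * vals
  if (!is.null(config$shift_genes)) {
    for (i in seq_len(nrow(config$shift_genes))) {
      g <- config$shift_genes$index[i]
      vals[g, group == "case"] <- vals[g, group == "case"] +
        config$shift_genes$shift[i] * config$noise_sd
    }
  }
  dimnames(vals) <- list(gids, sids)
  m <- expr_matrix(vals, group = group)

  truth <- structure(list(
    blocks = lapply(config$blocks, function(b) {
      list(genes = gids[b$gene_indices], category = b$category,
           rho_in = b$rho_in, active_group = b$active_group)
    }),
    de_genes = if (is.null(config$shift_genes)) character(0)
               else gids[unique(config$shift_genes$index)],
    category_map = stats::setNames(config$category_map, gids)
  ), class = "synthetic_truth")

  list(matrix = m, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Writes the expression TSV, the sample metadata TSV, and the ground truth
#' as JSON (block memberships, differentially expressed genes, category map).
#'
#' @param dataset the list returned by [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(dataset$matrix, paths[["expression"]], paths[["metadata"]])
  jsonlite::write_json(unclass(dataset$truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
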