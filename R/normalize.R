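#' Log2-transform an expression matrix
#'
#' Applied to linear-scale intensities before quantile normalization.
#'
#' @param m an [expr_matrix()] with strictly positive values.
#' @return an `expr_matrix` with each value x replaced by log2(x).
#' @export
log2_transform <- function(m) {
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort_fmt("nonpositive value(s) at e.g. gene %s, sample %s",
              gene_ids(m)[bad[1L, 1L]], sample_ids(m)[bad[1L, 2L]])
  }
  out <- m
  out$values <- log2(m$values)
  out
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the same empirical distribution: each
#' column's sorted values are replaced by the row-wise mean of all sorted
#' columns, assigned back by rank (ties receive the average of their target
#' quantiles). Delegates to [limma::normalizeQuantiles()]. The operation is
#' idempotent.
#'
#' @param m an [expr_matrix()] with at least two samples.
#' @return the normalized `expr_matrix`.
#' @export
quantile_normalize <- function(m) {
  if (n_samples(m) < 2L) abort_fmt("quantile normalization needs >=2 samples")
  out <- m
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  out$values <- v
  out
}

#' Collapse probe-level rows to gene-level rows
#'
#' For every gene keeps the probe with the maximal mean expression across
#' samples (ties broken by lexicographic probe ID); probes without a mapping
#' are dropped.
#'
#' @param m an [expr_matrix()] whose rownames are probe IDs.
#' @param probe_to_gene named character vector mapping probe ID -> gene
#'   symbol, or a two-column data.frame (probe, gene).
#' @return an `expr_matrix` with one row per mapped gene.
#' @export
collapse_probes <- function(m, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene[[2L]]),
                           as.character(probe_to_gene[[1L]]))
  } else {
    map <- probe_to_gene
  }
  if (length(map) == 0L) abort_fmt("empty probe-to-gene mapping")
  probes <- intersect(gene_ids(m), names(map))
  if (length(probes) == 0L) abort_fmt("no probe of the matrix is mapped")
  genes <- map[probes]
  means <- rowMeans(m$values[probes, , drop = FALSE])
  # max-mean rule, lexicographic probe ID on ties
  ord <- order(genes, -means, probes)
  keep <- probes[ord][!duplicated(genes[ord])]
  vals <- m$values[keep, , drop = FALSE]
  rownames(vals) <- unname(map[keep])
  expr_matrix(vals, group = m$group, outcome = m$outcome)
}

#' Balanced random subsampling of case samples
#'
#' Randomly selects, without replacement, as many case samples as there are
#' controls, so that the two groups entering the correlation matrix are of
#' equal size (a balanced correlation design). All control samples are
#' retained. Column order of the retained samples is preserved.
#'
#' @param m an [expr_matrix()] with at least as many cases as controls.
#' @param seed integer seed controlling the random draw.
#' @return an `expr_matrix` with `n_control` controls and `n_control` cases.
#' @export
balanced_subsample <- function(m, seed) {
  ctrl <- which(m$group == "control")
  case <- which(m$group == "case")
  if (length(case) < length(ctrl)) {
    abort_fmt("fewer cases (%d) than controls (%d); nothing to balance",
              length(case), length(ctrl))
  }
  picked <- with_seed(seed, sample(case, length(ctrl), replace = FALSE))
  keep <- sort(c(ctrl, picked))
  subset_samples_(m, keep)
}
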