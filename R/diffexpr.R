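#' Per-gene Welch t-test between case and control samples
#'
#' Two-sided unequal-variance (Welch) t-test per gene, vectorized across the
#' matrix. Degenerate genes with zero variance in both groups get `t = 0,
#' p = 1` when the group means are equal and `|t| = Inf, p = 0` otherwise.
#'
#' @param m an [expr_matrix()] with at least 2 samples per group.
#' @param fdr_threshold q-value cutoff for the `significant` flag.
#' @return data.frame with one row per gene: `gene`, `t`, `df`, `p`, `q`
#'   (Benjamini-Hochberg adjusted), `log2fc` (case mean - control mean, the
#'   log2 fold change on log-scale data) and `significant` (q <
#'   `fdr_threshold`).
#' @export
welch_t <- function(m, fdr_threshold = 0.01) {
  ctrl <- m$values[, m$group == "control", drop = FALSE]
  case <- m$values[, m$group == "case", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(case)
  if (n1 < 2L || n2 < 2L) {
    abort_fmt("need >= 2 samples per group (control %d, case %d)", n1, n2)
  }
  m1 <- rowMeans(ctrl); m2 <- rowMeans(case)
  v1 <- rowSums((ctrl - m1)^2) / (n1 - 1L)
  v2 <- rowSums((case - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  # both groups constant: equal means -> no evidence; unequal -> infinite t
  flat <- se2 == 0
  tstat[flat & (m1 == m2)] <- 0
  tstat[flat & (m1 != m2)] <- sign(m2 - m1)[flat & (m1 != m2)] * Inf
  df[flat] <- n1 + n2 - 2L
  p <- 2 * stats::pt(-abs(tstat), df)
  p[flat & (m1 == m2)] <- 1
  q <- bh_fdr(p)
  data.frame(gene = gene_ids(m), t = tstat, df = df, p = p, q = q,
             log2fc = m2 - m1, significant = q < fdr_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (wraps [stats::p.adjust()] after
#' input validation): q-values are capped at 1 and monotone non-decreasing in
#' the order of sorted p-values.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    abort_fmt("p-values must all lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene set enrichment with a GAGE-style per-sample t statistic
#'
#' For each case sample, per-gene log fold changes against the mean of the
#' control group are computed. For each gene set, a two-sample Welch t
#' statistic compares the set's fold changes with those of all other genes in
#' that sample, yielding a one-sided p-value per case sample and direction.
#' Per-sample p-values are combined into a global p-value with Stouffer's
#' method, using a covariance-corrected denominator
#' `sqrt(m + m (m - 1) rho)` with `rho = (1/n_ctrl) / (1 + 1/n_ctrl)`:
#' because every case sample's fold changes reuse the same control mean, the
#' per-sample statistics are positively correlated, and the plain `sqrt(m)`
#' denominator would be anti-conservative.
#'
#' @param m an [expr_matrix()] with >= 1 sample per group.
#' @param gene_sets named list of character vectors (e.g.
#'   `registry$gene_sets`), or a `pathway_registry`.
#' @param alpha global p-value threshold for the `significant` flag.
#' @param min_overlap minimum number of set genes present in the matrix;
#'   smaller sets are skipped with a warning.
#' @return data.frame with one row per gene set x direction (`up`, `down`):
#'   `pathway`, `direction`, `stat` (mean per-sample t), `set_size` (genes in
#'   the matrix), `global_p` and `significant`.
#' @export
gage_enrichment <- function(m, gene_sets, alpha = 0.05, min_overlap = 2L) {
  if (inherits(gene_sets, "pathway_registry")) gene_sets <- gene_sets$gene_sets
  ctrl <- m$values[, m$group == "control", drop = FALSE]
  case <- m$values[, m$group == "case", drop = FALSE]
  if (ncol(ctrl) < 1L || ncol(case) < 1L) {
    abort_fmt("need >= 1 sample in each group")
  }
  fc <- case - rowMeans(ctrl)
  nsamp <- ncol(case)
  rho <- (1 / ncol(ctrl)) / (1 + 1 / ncol(ctrl))
  denom <- sqrt(nsamp + nsamp * (nsamp - 1) * rho)
  genes <- gene_ids(m)

  rows <- lapply(names(gene_sets), function(nm) {
    inset <- genes %in% gene_sets[[nm]]
    k <- sum(inset)
    if (k < min_overlap || k > length(genes) - 2L) {
      warn_fmt("skipping '%s': %d gene(s) overlap the matrix", nm, k)
      return(NULL)
    }
    tstats <- numeric(nsamp)
    p_up <- numeric(nsamp)
    for (s in seq_len(nsamp)) {
      x <- fc[inset, s]; y <- fc[!inset, s]
      v1 <- stats::var(x) / k
      v2 <- stats::var(y) / length(y)
      tt <- (mean(x) - mean(y)) / sqrt(v1 + v2)
      dfree <- (v1 + v2)^2 / (v1^2 / (k - 1) + v2^2 / (length(y) - 1))
      tstats[s] <- tt
      p_up[s] <- stats::pt(tt, dfree, lower.tail = FALSE)
    }
    z_up <- stats::qnorm(p_up, lower.tail = FALSE)
    gp_up <- stats::pnorm(sum(z_up) / denom, lower.tail = FALSE)
    gp_down <- stats::pnorm(sum(-z_up) / denom, lower.tail = FALSE)
    data.frame(pathway = nm, direction = c("up", "down"),
               stat = c(mean(tstats), -mean(tstats)), set_size = k,
               global_p = c(gp_up, gp_down),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(0), direction = character(0),
                      stat = numeric(0), set_size = integer(0),
                      global_p = numeric(0), stringsAsFactors = FALSE)
  }
  out$significant <- out$global_p < alpha
  rownames(out) <- NULL
  out
}

# abbreviations used in the report tables for the shipped KEGG pathway names
pathway_abbreviations <- function() {
  c("T cell receptor signaling pathway (hsa04660)" = "TCR",
    "B cell receptor signaling pathway (hsa04662)" = "BCR",
    "Antigen processing and presentation (hsa04612)" = "APC",
    "Complement and coagulation cascades (hsa04610)" = "C",
    "Fc epsilon RI signaling pathway (hsa04664)" = "Fc",
    "Fc gamma R-mediated phagocytosis (hsa04666)" = "Fc",
    "Hematopoietic cell lineage (hsa04640)" = "H",
    "Intestinal immune network for IgA production (hsa04672)" = "IgA",
    "Leukocyte transendothelial migration (hsa04670)" = "LM",
    "Natural killer cell mediated cytotoxicity (hsa04650)" = "NK",
    "RIG-I-like receptor signaling pathway (hsa04622)" = "RIG",
    "Toll-like receptor signaling pathway (hsa04620)" = "TLR",
    "Chemokine signaling pathway (hsa04062)" = "CXC & etc",
    "NOD-like receptor signaling pathway (hsa04621)" = "K")
}

#' Summarize significant pathways by direction
#'
#' Produces the up-regulated / down-regulated pathway lists of an enrichment
#' run, using the conventional abbreviations (TCR, APC, C, Fc, ...) where one
#' exists for the pathway name.
#'
#' @param enrichment result of [gage_enrichment()].
#' @param abbreviate use abbreviations where available.
#' @return list with elements `up` and `down` (character vectors, sorted,
#'   deduplicated) and `counts` (named integer vector).
#' @export
summarize_directions <- function(enrichment, abbreviate = TRUE) {
  abbr <- pathway_abbreviations()
  pick <- function(dir) {
    nm <- enrichment$pathway[enrichment$direction == dir &
                             enrichment$significant]
    if (abbreviate) {
      hit <- nm %in% names(abbr)
      nm[hit] <- abbr[nm[hit]]
    }
    sort(unique(nm))
  }
  up <- pick("up"); down <- pick("down")
  list(up = up, down = down,
       counts = c(up = length(up), down = length(down)))
}
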