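#' Expression matrix with sample groups
#'
#' The container passed between all pipeline stages: a genes x samples numeric
#' matrix on a log2-like scale together with a group label per sample
#' (`control` or `case`) and an optional outcome label (`survivor` /
#' `nonsurvivor`) used for the survivor-vs-nonsurvivor style analyses.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must have
#'   unique, non-empty rownames (gene IDs) and colnames (sample IDs).
#' @param group character or factor of length `ncol(values)` with values
#'   `"control"` or `"case"`.
#' @param outcome optional character of length `ncol(values)` with values
#'   `"survivor"`, `"nonsurvivor"` or `NA`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `group` (named character) and `outcome` (named character or `NULL`).
#' @export
#' @examples
#' m <- expr_matrix(matrix(1:6, 2, 3,
#'                         dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
#'                  group = c("control", "control", "case"))
#' n_samples(m)
expr_matrix <- function(values, group, outcome = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_fmt("`values` must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    abort_fmt("`values` must have non-empty gene IDs as rownames")
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    abort_fmt("`values` must have non-empty sample IDs as colnames")
  }
  dup_g <- unique(gid[duplicated(gid)])
  if (length(dup_g)) {
    abort_fmt("duplicate gene IDs: %s", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(sid[duplicated(sid)])
  if (length(dup_s)) {
    abort_fmt("duplicate sample IDs: %s", paste(dup_s, collapse = ", "))
  }
  group <- as.character(group)
  if (length(group) != ncol(values)) {
    abort_fmt("`group` must have one entry per sample")
  }
  bad <- setdiff(unique(group), c("control", "case"))
  if (length(bad)) {
    abort_fmt("unknown group labels: %s (expected control/case)",
              paste(bad, collapse = ", "))
  }
  names(group) <- sid
  if (!is.null(outcome)) {
    outcome <- as.character(outcome)
    if (length(outcome) != ncol(values)) {
      abort_fmt("`outcome` must have one entry per sample")
    }
    bad <- setdiff(unique(outcome[!is.na(outcome)]),
                   c("survivor", "nonsurvivor"))
    if (length(bad)) {
      abort_fmt("unknown outcome labels: %s", paste(bad, collapse = ", "))
    }
    names(outcome) <- sid
  }
  structure(list(values = values, group = group, outcome = outcome),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "control"), sum(x$group == "case")))
  if (!is.null(x$outcome)) {
    cat(sprintf("  outcome: %d survivor, %d nonsurvivor, %d NA\n",
                sum(x$outcome == "survivor", na.rm = TRUE),
                sum(x$outcome == "nonsurvivor", na.rm = TRUE),
                sum(is.na(x$outcome))))
  }
  invisible(x)
}

#' @rdname expr_matrix
#' @param m an `expr_matrix`.
#' @export
n_genes <- function(m) nrow(m$values)

#' @rdname expr_matrix
#' @export
n_samples <- function(m) ncol(m$values)

#' @rdname expr_matrix
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

# subset samples, keeping labels aligned
subset_samples_ <- function(m, keep) {
  expr_matrix(m$values[, keep, drop = FALSE],
              group = m$group[keep],
              outcome = if (is.null(m$outcome)) NULL else m$outcome[keep])
}

#' Select the samples of one group or outcome
#'
#' @param m an [expr_matrix()].
#' @param group one of `"control"`, `"case"`, `"survivor"`, `"nonsurvivor"`
#'   or `"all"`. Survivor/nonsurvivor select on the outcome labels (restricted
#'   to case samples).
#' @return an `expr_matrix` with the selected samples only.
#' @export
select_group <- function(m, group = c("all", "control", "case",
                                      "survivor", "nonsurvivor")) {
  group <- match.arg(group)
  if (group == "all") return(m)
  keep <- if (group %in% c("control", "case")) {
    m$group == group
  } else {
    if (is.null(m$outcome)) abort_fmt("matrix has no outcome labels")
    !is.na(m$outcome) & m$outcome == group & m$group == "case"
  }
  if (!any(keep)) abort_fmt("no samples in group '%s'", group)
  subset_samples_(m, which(keep))
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The expression file is tab separated with gene IDs in the first column and
#' one column per sample; the metadata file has columns `sample_id`, `group`
#' and optionally `outcome`. Genes containing any missing value are dropped
#' with a warning (correlations downstream require complete vectors).
#'
#' @param matrix_path path to the expression TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return an [expr_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) abort_fmt("expression file needs >=1 sample column")
  gid <- as.character(raw[[1L]])
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) {
    abort_fmt("duplicate gene IDs in %s: %s", matrix_path,
              paste(dup, collapse = ", "))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gid

  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(meta))) {
    abort_fmt("metadata must have columns: %s", paste(need, collapse = ", "))
  }
  missing_meta <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing_meta)) {
    abort_fmt("samples absent from metadata: %s",
              paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]

  incomplete <- rowSums(!is.finite(vals)) > 0L
  if (any(incomplete)) {
    warn_fmt("dropping %d gene(s) with missing values", sum(incomplete))
    vals <- vals[!incomplete, , drop = FALSE]
  }
  outcome <- if ("outcome" %in% names(meta)) {
    oc <- as.character(meta$outcome)
    oc[oc %in% c("", "NA")] <- NA_character_
    oc
  } else {
    NULL
  }
  expr_matrix(vals, group = meta$group, outcome = outcome)
}

#' Write an expression matrix and its metadata to TSV files
#'
#' Inverse of [read_expression()]: a write/read round trip reproduces the
#' matrix to full double precision (values are serialized with 17 significant
#' digits).
#'
#' @param m an [expr_matrix()].
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(m, matrix_path, metadata_path) {
  df <- data.frame(gene_id = gene_ids(m),
                   format(m$values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_(df, matrix_path)
  meta <- data.frame(sample_id = sample_ids(m),
                     group = unname(m$group),
                     outcome = if (is.null(m$outcome)) NA_character_
                               else unname(m$outcome),
                     stringsAsFactors = FALSE)
  write_tsv_(meta, metadata_path)
  invisible(c(matrix_path, metadata_path))
}
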