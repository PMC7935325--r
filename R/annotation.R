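#' The ten immune functional categories
#'
#' Every pathway of the registry maps to exactly one of these labels and every
#' annotated gene receives one of them (or `"U"`, undetermined, when the
#' majority rule ties out).
#'
#' @return character vector of the 10 category labels.
#' @export
immune_categories <- function() {
  c("adaptive immunity", "antigen presentation", "complement-coagulation",
    "cytokines-chemokines", "hematopoiesis", "innate immunity",
    "leukocyte migration", "NK cell activity", "platelet activity",
    "signaling")
}

# the trio deprioritized by the tie rule
tie_excluded_categories <- function() {
  c("cytokines-chemokines", "signaling", "hematopoiesis")
}

read_gmt_ <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}

#' Load a pathway registry from GMT files and a category map
#'
#' @param gmt_paths character vector of GMT file paths (standard format:
#'   pathway name, description, then tab-separated gene symbols).
#' @param category_map_path TSV with columns `pathway`, `source` (KEGG, GO or
#'   Reactome) and `category` (one of [immune_categories()]); must cover every
#'   pathway found in the GMT files.
#' @return a `pathway_registry`: list with `pathways` (data.frame pathway /
#'   source / category) and `gene_sets` (named list of character vectors).
#' @export
load_registry <- function(gmt_paths, category_map_path) {
  sets <- list()
  for (p in gmt_paths) sets <- c(sets, read_gmt_(p))
  if (anyDuplicated(names(sets))) {
    abort_fmt("duplicate pathway names across GMT files: %s",
              paste(unique(names(sets)[duplicated(names(sets))]),
                    collapse = ", "))
  }
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    abort_fmt("empty gene set(s): %s", paste(empty, collapse = ", "))
  }
  cmap <- utils::read.delim(category_map_path, stringsAsFactors = FALSE)
  need <- c("pathway", "source", "category")
  if (!all(need %in% names(cmap))) {
    abort_fmt("category map must have columns: %s", paste(need, collapse = ", "))
  }
  missing <- setdiff(names(sets), cmap$pathway)
  if (length(missing)) {
    abort_fmt("pathway(s) missing from category map: %s",
              paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(cmap$category), immune_categories())
  if (length(bad)) {
    abort_fmt("unknown categories in map: %s", paste(bad, collapse = ", "))
  }
  cmap <- cmap[match(names(sets), cmap$pathway), need]
  rownames(cmap) <- NULL
  structure(list(pathways = cmap, gene_sets = sets),
            class = "pathway_registry")
}

#' @export
print.pathway_registry <- function(x, ...) {
  cat(sprintf("<pathway_registry> %d pathways (%s), %d categories, %d genes\n",
              nrow(x$pathways),
              paste(sprintf("%s: %d", names(table(x$pathways$source)),
                            table(x$pathways$source)), collapse = ", "),
              length(unique(x$pathways$category)),
              length(registry_genes(x))))
  invisible(x)
}

#' Genes covered by a registry
#'
#' @param registry a `pathway_registry`.
#' @return sorted character vector: the union of all pathway gene sets.
#' @export
registry_genes <- function(registry) {
  sort(unique(unlist(registry$gene_sets, use.names = FALSE)))
}

#' The shipped default immune pathway registry
#'
#' Loads the registry distributed with the package: the 21 KEGG immune-system
#' pathways plus the GO and Reactome gene sets used for annotation votes, each
#' mapped to one of the 10 functional categories. The member gene lists are a
#' reduced synthetic stand-in (see the fixture filenames) sufficient for the
#' annotation logic and tests; users can load the full published lists with
#' [load_registry()].
#'
#' @return a `pathway_registry`.
#' @export
default_registry <- function() {
  ext <- system.file("extdata", package = "sepnet")
  load_registry(
    gmt_paths = file.path(ext, c("kegg_immune_synthetic.gmt",
                                 "go_immune_synthetic.gmt",
                                 "reactome_immune_synthetic.gmt")),
    category_map_path = file.path(ext, "pathway_categories.tsv")
  )
}

#' Assign one functional category to a gene by majority vote
#'
#' Each pathway that contains the gene casts one vote for its category. The
#' category with the strictly highest vote count wins. On a tie, two rules
#' apply: (1) if the tied set mixes categories inside and outside the trio
#' cytokines-chemokines / signaling / hematopoiesis, the trio members are
#' removed and the remainder re-evaluated; (2) any tie that survives (all
#' tied outside the trio, all tied inside it, or several survivors after
#' rule 1) yields `"U"` (undetermined).
#'
#' @param gene gene symbol.
#' @param registry a `pathway_registry`.
#' @return single category label or `"U"`.
#' @export
assign_category <- function(gene, registry) {
  hit <- vapply(registry$gene_sets, function(s) gene %in% s, logical(1L))
  if (!any(hit)) abort_fmt("gene '%s' not found in any registry pathway", gene)
  votes <- table(registry$pathways$category[hit])
  resolve_vote_tie_(votes)
}

resolve_vote_tie_ <- function(votes) {
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  outside <- setdiff(top, tie_excluded_categories())
  if (length(outside) >= 1L && length(outside) < length(top)) top <- outside
  if (length(top) == 1L) top else "U"
}

#' Annotate every gene of a registry
#'
#' @param registry a `pathway_registry`.
#' @return a named character vector (class `gene_annotation`): gene ->
#'   category label (or `"U"`), covering the union of all pathway gene sets,
#'   with the category frequency table attached as attribute `"frequencies"`.
#' @export
annotate_all <- function(registry) {
  genes <- registry_genes(registry)
  cats <- registry$pathways$category
  # membership matrix: pathways x genes, then one vote tally per gene
  labels <- vapply(genes, function(g) {
    hit <- vapply(registry$gene_sets, function(s) g %in% s, logical(1L))
    resolve_vote_tie_(table(cats[hit]))
  }, character(1L))
  structure(labels, frequencies = table(labels), class = "gene_annotation")
}

#' Write a gene annotation to TSV
#'
#' @param annotation result of [annotate_all()] (or any named character
#'   vector gene -> category).
#' @param path output TSV path (columns `gene`, `category`).
#' @return invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_(data.frame(gene = names(annotation),
                        category = as.character(unname(annotation)),
                        stringsAsFactors = FALSE), path)
}
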