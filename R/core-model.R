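# Core domain model: gene symbols, pathways, pathway databases, gene universes.
#
# Pathways are treated purely as named gene sets (no topology). Gene symbols
# are HGNC-style plain tokens; the only normalization applied is whitespace
# stripping and uppercasing, because GMT exports vary in case. No identifier
# mapping service is consulted.

#' Normalize a gene symbol
#'
#' Strips surrounding whitespace and uppercases, yielding the canonical form
#' under which all gene comparisons in the package are performed. Symbols
#' differing only in case compare equal after normalization. The function is
#' idempotent and vectorised.
#'
#' @param raw Character vector of raw gene symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_gene_symbol(c("snca", " CASP3 "))
#' @export
normalize_gene_symbol <- function(raw) {
  if (!is.character(raw)) {
    abort_validation("gene symbols must be character")
  }
  out <- toupper(trimws(raw))
  if (any(!nzchar(out)) || anyNA(out)) {
    abort_validation("gene symbol is empty (or NA) after stripping whitespace")
  }
  if (any(grepl("[\t\n ]", out))) {
    abort_validation("gene symbol contains internal whitespace")
  }
  out
}

#' Construct a pathway (a named gene set from one resource)
#'
#' Genes are normalized with [normalize_gene_symbol()] and deduplicated; the
#' stored gene set is sorted for reproducible output. An empty gene set is
#' representable but triggers a warning so readers can flag rather than fail.
#'
#' @param resource Database name (non-empty).
#' @param pathway_id Identifier, unique within the resource (non-empty).
#' @param name Human-readable pathway name.
#' @param genes Character vector of raw gene symbols (may be empty).
#' @param imported Flag marking a pathway a database imported from another
#'   resource (such pathways are skipped by mapping suggestion).
#' @return An object of class `pathway` with fields `resource`, `pathway_id`,
#'   `name`, `genes`, `imported`.
#' @examples
#' p <- pathway("KEGG", "hsa04210", "Apoptosis", c("CASP3", "casp3", "CYCS"))
#' p$genes
#' @export
pathway <- function(resource, pathway_id, name = pathway_id, genes = character(),
                    imported = FALSE) {
  if (!is.character(resource) || length(resource) != 1L || !nzchar(trimws(resource))) {
    abort_validation("pathway resource must be a non-empty string")
  }
  if (!is.character(pathway_id) || length(pathway_id) != 1L || !nzchar(trimws(pathway_id))) {
    abort_validation("pathway_id must be a non-empty string")
  }
  genes <- as.character(genes)
  genes <- genes[nzchar(trimws(genes))]
  if (length(genes) > 0L) {
    genes <- sort(unique(normalize_gene_symbol(genes)))
  } else {
    warn_pathmapr(
      sprintf("pathway '%s' (%s) has an empty gene set", pathway_id, resource),
      class = "pathmapr_empty_geneset_warning"
    )
    genes <- character()
  }
  structure(
    list(
      resource = resource,
      pathway_id = pathway_id,
      name = as.character(name),
      genes = genes,
      imported = isTRUE(imported)
    ),
    class = "pathway"
  )
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf(
    "<pathway> %s:%s \"%s\" (%d genes)\n",
    x$resource, x$pathway_id, x$name, length(x$genes)
  ))
  invisible(x)
}

#' Stable reference key "resource:pathway_id" for a pathway
#'
#' @param x A `pathway`, or a list of pathways.
#' @return Character vector of keys.
#' @export
pathway_key <- function(x) {
  if (inherits(x, "pathway")) {
    return(paste0(x$resource, ":", x$pathway_id))
  }
  unname(vapply(x, function(p) paste0(p$resource, ":", p$pathway_id), character(1)))
}

#' Construct a pathway database
#'
#' A versioned, named collection of pathways from a single resource. All
#' member pathways must carry the database's resource label and their ids
#' must be unique.
#'
#' @param resource Database name.
#' @param version Free-form version label (e.g. a release date).
#' @param pathways List of `pathway` objects.
#' @return Object of class `pathway_database` with fields `resource`,
#'   `version`, `pathways` (named list keyed by pathway_id).
#' @export
pathway_database <- function(resource, version = "unversioned", pathways = list()) {
  if (!is.character(resource) || length(resource) != 1L || !nzchar(resource)) {
    abort_validation("database resource must be a non-empty string")
  }
  res <- vapply(pathways, function(p) p$resource, character(1))
  if (length(res) && any(res != resource)) {
    abort_validation(sprintf(
      "all pathways must have resource '%s' (found: %s)",
      resource, paste(unique(res[res != resource]), collapse = ", ")
    ))
  }
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  if (anyDuplicated(ids)) {
    abort_validation(sprintf(
      "duplicate pathway_id in %s: %s",
      resource, paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  names(pathways) <- ids
  structure(
    list(resource = resource, version = as.character(version), pathways = pathways),
    class = "pathway_database"
  )
}

#' @export
print.pathway_database <- function(x, ...) {
  cat(sprintf(
    "<pathway_database> %s (version %s): %d pathways, %d distinct genes\n",
    x$resource, x$version, length(x$pathways), length(database_genes(x))
  ))
  invisible(x)
}

#' Number of pathways in a database
#' @param x A `pathway_database`.
#' @export
n_pathways <- function(x) length(x$pathways)

#' Union of all gene symbols annotated in a database
#'
#' @param db A `pathway_database`.
#' @return Sorted character vector of distinct gene symbols.
#' @export
database_genes <- function(db) {
  if (length(db$pathways) == 0L) return(character())
  sort(unique(unlist(lapply(db$pathways, `[[`, "genes"), use.names = FALSE)))
}

#' Construct a gene universe
#'
#' The background gene set against which coverage and enrichment are
#' computed (e.g. all HGNC-approved symbols).
#'
#' @param genes Character vector of raw gene symbols (non-empty).
#' @param label Text label for the universe.
#' @return Object of class `gene_universe`.
#' @export
gene_universe <- function(genes, label = "universe") {
  genes <- as.character(genes)
  genes <- genes[nzchar(trimws(genes))]
  if (length(genes) == 0L) {
    abort_validation("gene universe must be non-empty")
  }
  structure(
    list(genes = sort(unique(normalize_gene_symbol(genes))), label = as.character(label)),
    class = "gene_universe"
  )
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("<gene_universe> %s: %d genes\n", x$label, length(x$genes)))
  invisible(x)
}
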