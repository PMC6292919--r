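# Over-representation analysis: one-sided Fisher's exact test of a query
# gene list against every pathway in one or more databases, with
# Benjamini-Yekutieli FDR control (valid under dependency — pathway gene
# sets overlap heavily) and three rule-based filters: minimum query
# overlap, maximum pathway size, and a q-value threshold.
#
# The 2x2 table per pathway is [in-query & in-pathway, in-query & not,
# not-in-query & in-pathway, neither] over the background universe; the
# one-sided (greater) p-value is the hypergeometric upper-tail
# P(X >= overlap) with X ~ Hypergeom(N = universe, K = pathway size,
# n = query size).

#' Fisher's exact test enrichment of a query gene set
#'
#' Tests every pathway in the supplied databases for over-representation of
#' the query genes. The background defaults to the union of all genes
#' annotated in the queried databases; an explicit [gene_universe()] may
#' override it, in which case pathway gene sets are restricted to it. Query
#' genes outside the background are dropped with a warning. Pathways with
#' zero overlap are still reported. P-values are unadjusted; see
#' [adjust_benjamini_yekutieli()] and [enrichment_pipeline()].
#'
#' @param query Character vector of query gene symbols.
#' @param dbs A [pathway_database()] or list of them.
#' @param universe Optional [gene_universe()] background.
#' @return Data.frame (one row per pathway) with columns `resource`,
#'   `pathway_id`, `name`, `overlap_count`, `pathway_size`,
#'   `query_size_in_universe`, `universe_size`, `p_value`.
#' @export
fisher_enrichment <- function(query, dbs, universe = NULL) {
  dbs <- as_database_list(dbs)
  query <- unique(normalize_gene_symbol(as.character(query)))
  background <- if (is.null(universe)) {
    sort(unique(unlist(lapply(dbs, database_genes), use.names = FALSE)))
  } else {
    stopifnot(inherits(universe, "gene_universe"))
    universe$genes
  }
  if (length(background) == 0L) {
    abort_validation("enrichment background is empty")
  }
  dropped <- setdiff(query, background)
  if (length(dropped) > 0L) {
    warn_pathmapr(sprintf(
      "%d query gene(s) absent from the background were dropped: %s",
      length(dropped), paste(utils::head(dropped, 5), collapse = ", ")
    ))
  }
  query <- intersect(query, background)
  if (length(query) == 0L) {
    abort_validation("no query genes remain after restriction to the background")
  }

  rows <- lapply(dbs, function(db) {
    ps <- sorted_pathways(db)
    if (length(ps) == 0L) return(NULL)
    data.frame(
      resource = db$resource,
      pathway_id = vapply(ps, `[[`, character(1), "pathway_id"),
      name = vapply(ps, `[[`, character(1), "name"),
      pathway_size = vapply(ps, function(p) {
        length(intersect(p$genes, background))
      }, integer(1)),
      overlap_count = vapply(ps, function(p) {
        length(intersect(intersect(p$genes, background), query))
      }, integer(1)),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    abort_validation("no pathways to test: all databases are empty")
  }
  rownames(res) <- NULL
  N <- length(background)
  n <- length(query)
  res$p_value <- enrichment_p_value(res$overlap_count, res$pathway_size, n, N)
  res$query_size_in_universe <- n
  res$universe_size <- N
  res[, c("resource", "pathway_id", "name", "overlap_count", "pathway_size",
          "query_size_in_universe", "universe_size", "p_value")]
}

#' One-sided enrichment p-value for a 2x2 overlap table
#'
#' The p-value of Fisher's exact test with the `greater` alternative for
#' the table (in-query & in-pathway, in-query & not, not & in-pathway,
#' neither): the hypergeometric upper tail `P(X >= overlap)` with
#' `X ~ Hypergeom(universe_size, pathway_size, query_size)`. Vectorised
#' over all four arguments.
#'
#' @param overlap Number of query genes in the pathway.
#' @param pathway_size,query_size,universe_size Marginals of the table.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @export
enrichment_p_value <- function(overlap, pathway_size, query_size, universe_size) {
  if (any(overlap < 0 | overlap > pmin(pathway_size, query_size))) {
    abort_validation("overlap must lie in [0, min(pathway_size, query_size)]")
  }
  stats::phyper(overlap - 1L, pathway_size, universe_size - pathway_size,
                query_size, lower.tail = FALSE)
}

as_database_list <- function(dbs) {
  if (inherits(dbs, "pathway_database")) dbs <- list(dbs)
  if (length(dbs) == 0L || !all(vapply(dbs, inherits, logical(1), "pathway_database"))) {
    abort_validation("dbs must be a pathway_database or a list of them")
  }
  dbs
}

#' Benjamini-Yekutieli step-up FDR adjustment
#'
#' Computes q-values controlling the false discovery rate under arbitrary
#' dependency: `q_(i) = min over j >= i of min(1, p_(j) * m * c(m) / j)`
#' with `c(m) = sum_{k=1..m} 1/k`. More conservative than
#' Benjamini-Hochberg by the factor `c(m)`. Output order matches input
#' order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
adjust_benjamini_yekutieli <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BY")
}

FILTER_REASONS <- c("too_few_query_genes", "pathway_too_large", "not_significant")

#' Apply the three enrichment filtering rules
#'
#' A result passes iff it has at least `min_query_overlap` query genes,
#' its pathway has at most `max_pathway_size` genes, and its q-value is at
#' most `q_threshold`. The defaults (2, 300, 0.05) discard pathways with
#' fewer than two query genes, larger than 300 genes, or with FDR above
#' 5%; boundaries are inclusive-pass since the discard rules are strict
#' exceedances. All failing reasons are recorded independently.
#'
#' @param results Data.frame from [fisher_enrichment()] with a `q_value`
#'   column already added.
#' @param min_query_overlap Minimum query genes in the pathway (default 2).
#' @param max_pathway_size Maximum pathway size (default 300).
#' @param q_threshold FDR threshold (default 0.05).
#' @return The input with added columns `passes_filters` (logical) and
#'   `filter_reasons` (comma-separated string, empty when passing).
#' @export
apply_filters <- function(results, min_query_overlap = 2L,
                          max_pathway_size = 300L, q_threshold = 0.05) {
  stopifnot(is.data.frame(results), "q_value" %in% names(results))
  reasons <- mapply(function(overlap, size, q) {
    r <- character()
    if (overlap < min_query_overlap) r <- c(r, "too_few_query_genes")
    if (size > max_pathway_size) r <- c(r, "pathway_too_large")
    if (q > q_threshold) r <- c(r, "not_significant")
    paste(r, collapse = ",")
  }, results$overlap_count, results$pathway_size, results$q_value,
  USE.NAMES = FALSE)
  results$passes_filters <- !nzchar(reasons)
  results$filter_reasons <- reasons
  results
}

#' Full enrichment pipeline: test, adjust, filter, sort
#'
#' Composes [fisher_enrichment()], [adjust_benjamini_yekutieli()] (applied
#' jointly across all tested pathways, one hypothesis family per run) and
#' [apply_filters()], sorting by q-value, then p-value, then resource and
#' pathway_id so the output is invariant to database order.
#'
#' @inheritParams fisher_enrichment
#' @inheritParams apply_filters
#' @return Annotated data.frame; every tested pathway is retained, with
#'   `passes_filters` marking the surviving ones.
#' @export
enrichment_pipeline <- function(query, dbs, universe = NULL,
                                min_query_overlap = 2L,
                                max_pathway_size = 300L,
                                q_threshold = 0.05) {
  res <- fisher_enrichment(query, dbs, universe)
  res$q_value <- adjust_benjamini_yekutieli(res$p_value)
  res <- apply_filters(res, min_query_overlap, max_pathway_size, q_threshold)
  res <- res[order(res$q_value, res$p_value, res$resource, res$pathway_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write enrichment results to TSV
#'
#' @param results Data.frame from [enrichment_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
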