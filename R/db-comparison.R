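# Database-level descriptive statistics: Euler-style gene-coverage
# partitions across resources, pathway-size distributions, gene promiscuity
# (how many pathways each gene belongs to), and count(k) curves of pathways
# sharing at least k genes with a reference set.

#' Partition a gene universe by database membership
#'
#' Assigns each universe gene to exactly one disjoint region according to
#' which databases annotate it (e.g. "KEGG", "KEGG&Reactome", or "none"),
#' the partition underlying an Euler/Venn diagram of gene-centric coverage.
#' Database genes absent from the universe do not enter the partition; their
#' count is reported via a warning and stored in the result.
#'
#' @param dbs List of [pathway_database()] objects (at least one), with
#'   distinct resource names.
#' @param universe A [gene_universe()].
#' @return Object of class `coverage_partition`: list with `region_counts`
#'   (named integer vector over subset signatures plus `"none"`, summing to
#'   the universe size), `universe_label`, `universe_size`, and
#'   `outside_universe` (count of database genes not in the universe).
#' @export
gene_coverage_partition <- function(dbs, universe) {
  stopifnot(length(dbs) >= 1L, inherits(universe, "gene_universe"))
  resources <- vapply(dbs, `[[`, character(1), "resource")
  if (anyDuplicated(resources)) {
    abort_validation("databases must have distinct resource names")
  }
  gene_sets <- lapply(dbs, database_genes)
  names(gene_sets) <- resources

  membership <- vapply(
    gene_sets, function(g) universe$genes %in% g,
    logical(length(universe$genes))
  )
  membership <- matrix(membership, nrow = length(universe$genes),
                       dimnames = list(NULL, resources))
  signature <- apply(membership, 1L, function(row) {
    if (!any(row)) "none" else paste(resources[row], collapse = "&")
  })
  region_counts <- table(signature)
  region_counts <- stats::setNames(as.integer(region_counts), names(region_counts))

  outside <- length(setdiff(unique(unlist(gene_sets, use.names = FALSE)),
                            universe$genes))
  if (outside > 0L) {
    warn_pathmapr(sprintf(
      "%d database gene(s) absent from universe '%s' were excluded from the partition",
      outside, universe$label
    ))
  }
  structure(
    list(
      region_counts = region_counts,
      universe_label = universe$label,
      universe_size = length(universe$genes),
      outside_universe = outside
    ),
    class = "coverage_partition"
  )
}

#' @export
print.coverage_partition <- function(x, ...) {
  cat(sprintf("<coverage_partition> universe %s (%d genes)\n",
              x$universe_label, x$universe_size))
  for (nm in names(sort(x$region_counts, decreasing = TRUE))) {
    cat(sprintf("  %-30s %d\n", nm, x$region_counts[[nm]]))
  }
  invisible(x)
}

#' Export a coverage partition as JSON
#'
#' Emits the region-to-count map in a form consumable by Euler-diagram
#' renderers.
#'
#' @param partition A `coverage_partition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coverage_json <- function(partition, path) {
  jsonlite::write_json(
    list(
      universe = partition$universe_label,
      universe_size = partition$universe_size,
      outside_universe = partition$outside_universe,
      regions = as.list(partition$region_counts)
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Summarize the pathway-size distribution of a database
#'
#' Mean, median, min and max of gene-set sizes plus a deterministic
#' histogram: unit-width integer bins up to size 50, then geometric bins
#' (edge ratio 1.5) until the maximum size is covered.
#'
#' @param db A non-empty [pathway_database()].
#' @return List with `resource`, `n_pathways`, `mean`, `median`, `min`,
#'   `max`, and `histogram` (data.frame with `bin_start`, `bin_end`,
#'   `count`; bins are `[start, end)` except the last, which is closed).
#' @export
pathway_size_summary <- function(db) {
  stopifnot(inherits(db, "pathway_database"))
  if (n_pathways(db) == 0L) {
    abort_validation("pathway_size_summary requires a non-empty database")
  }
  sizes <- vapply(db$pathways, function(p) length(p$genes), integer(1))
  breaks <- size_histogram_breaks(max(sizes))
  bins <- cut(sizes, breaks = breaks, right = FALSE, include.lowest = TRUE)
  hist <- data.frame(
    bin_start = breaks[-length(breaks)],
    bin_end = breaks[-1],
    count = as.integer(table(bins)),
    stringsAsFactors = FALSE
  )
  list(
    resource = db$resource,
    n_pathways = length(sizes),
    mean = mean(sizes),
    median = stats::median(sizes),
    min = min(sizes),
    max = max(sizes),
    histogram = hist
  )
}

# Unit bins [0,1), [1,2), ... up to 50, then geometric with ratio 1.5.
size_histogram_breaks <- function(max_size) {
  breaks <- 0:max(50L, 1L)
  while (breaks[length(breaks)] <= max_size) {
    breaks <- c(breaks, ceiling(breaks[length(breaks)] * 1.5))
  }
  breaks
}

#' Gene promiscuity: pathways per gene
#'
#' Counts, for every gene annotated somewhere in the supplied databases,
#' the number of distinct pathways that contain it. Genes absent from all
#' pathways do not appear.
#'
#' @param dbs List of [pathway_database()] objects (at least one).
#' @return Data.frame with columns `gene`, `n_pathways`, sorted by
#'   decreasing count then gene symbol.
#' @export
gene_promiscuity <- function(dbs) {
  stopifnot(length(dbs) >= 1L)
  genes <- unlist(
    lapply(dbs, function(db) lapply(db$pathways, `[[`, "genes")),
    use.names = FALSE
  )
  if (length(genes) == 0L) {
    return(data.frame(gene = character(), n_pathways = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- table(genes)
  out <- data.frame(
    gene = names(counts),
    n_pathways = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_pathways, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathways sharing at least k genes with a reference set
#'
#' Returns the pathways whose intersection with `reference` has size at
#' least `k`; the count is non-increasing in `k`, tracing the
#' common-gene-count curve of a database against a reference gene set.
#'
#' @param db A [pathway_database()].
#' @param reference Character vector of gene symbols (normalized
#'   internally).
#' @param k Minimum number of shared genes (positive integer).
#' @return List with `count`, `k`, and `pathway_ids` (sorted).
#' @export
pathways_with_common_genes <- function(db, reference, k = 1L) {
  stopifnot(inherits(db, "pathway_database"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != as.integer(k)) {
    abort_validation("k must be a positive integer")
  }
  reference <- unique(normalize_gene_symbol(as.character(reference)))
  hits <- vapply(db$pathways, function(p) {
    length(intersect(p$genes, reference)) >= k
  }, logical(1))
  ids <- sort(names(hits)[hits])
  list(count = length(ids), k = as.integer(k), pathway_ids = ids)
}
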