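# Pathway cross-talk analysis: a weighted pathway-pathway similarity graph
# (edge weight = overlap coefficient of the endpoint gene sets), modules as
# connected components after removing edges below a weight threshold
# (default 0.2), multi-set overlap regions, and average-linkage hierarchical
# clustering on distance 1 - S with cophenetic closest-module assignment.

#' Build a thresholded pathway similarity network
#'
#' Nodes are pathways; an undirected edge with weight
#' `overlap_coefficient(genes_i, genes_j)` connects every pair whose weight
#' is at least `min_weight` (edges strictly below the threshold are
#' removed; equality is kept). Zero-weight and self edges are never stored.
#'
#' @param pathways List of [pathway()] objects (at least two, distinct
#'   keys).
#' @param min_weight Minimum edge weight retained (default 0.2).
#' @return Object of class `pathway_network`: list with `graph` (an
#'   [igraph::graph] with vertex attribute `name` = pathway key and edge
#'   attribute `weight`), `pathways` (named by key), `threshold`.
#' @export
build_network <- function(pathways, min_weight = 0.2) {
  if (length(pathways) < 2L) {
    abort_validation("build_network requires at least two pathways")
  }
  keys <- pathway_key(pathways)
  if (anyDuplicated(keys)) {
    abort_validation("pathways must have distinct (resource, pathway_id)")
  }
  names(pathways) <- keys
  ord <- order(keys)
  pathways <- pathways[ord]
  keys <- keys[ord]

  n <- length(pathways)
  from <- character(0); to <- character(0); w <- numeric(0)
  suppressWarnings(
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- overlap_coefficient(pathways[[i]]$genes, pathways[[j]]$genes)
        if (s > 0 && s >= min_weight) {
          from <- c(from, keys[i]); to <- c(to, keys[j]); w <- c(w, s)
        }
      }
    }
  )
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = keys)
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  }
  structure(
    list(graph = g, pathways = pathways, threshold = min_weight),
    class = "pathway_network"
  )
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("<pathway_network> %d pathways, %d edges (weight >= %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' Detect pathway modules as connected components
#'
#' A module is a connected component of the thresholded network with at
#' least two pathways; isolated pathways are reported as unassigned.
#' Modules are numbered M1, M2, ... by decreasing size, ties broken by the
#' lexicographically smallest member key, so the labelling is
#' deterministic.
#'
#' @param net A `pathway_network` from [build_network()].
#' @return Object of class `module_partition`: list with `modules` (named
#'   list, module id -> character vector of pathway keys) and `unassigned`
#'   (character vector of keys).
#' @export
detect_modules <- function(net) {
  stopifnot(inherits(net, "pathway_network"))
  comp <- igraph::components(net$graph)
  keys <- igraph::V(net$graph)$name
  groups <- split(keys, comp$membership)
  groups <- lapply(groups, sort)
  is_module <- vapply(groups, length, integer(1)) >= 2L
  modules <- groups[is_module]
  ord <- order(-vapply(modules, length, integer(1)),
               vapply(modules, `[[`, character(1), 1L))
  modules <- modules[ord]
  names(modules) <- if (length(modules)) paste0("M", seq_along(modules)) else character()
  unassigned <- sort(unlist(groups[!is_module], use.names = FALSE))
  structure(
    list(modules = modules, unassigned = as.character(unassigned)),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, %d unassigned\n",
              length(x$modules), length(x$unassigned)))
  for (m in names(x$modules)) {
    cat(sprintf("  %s: %s\n", m, paste(x$modules[[m]], collapse = ", ")))
  }
  invisible(x)
}

#' Genes common to all pathways of a module
#'
#' The intersection of the member gene sets — the shared core that mediates
#' the module's cross-talk.
#'
#' @param pathways Non-empty list of [pathway()] objects.
#' @return Sorted character vector (possibly empty).
#' @export
module_core_genes <- function(pathways) {
  if (length(pathways) == 0L) {
    abort_validation("module_core_genes requires at least one pathway")
  }
  sort(Reduce(intersect, lapply(pathways, `[[`, "genes")))
}

#' Disjoint overlap regions of a small pathway collection
#'
#' Assigns every gene in the union of the input gene sets to exactly one
#' subset signature (e.g. `"P1"`, `"P1&P3"`), the partition behind a
#' pathway-overlap Euler view. Counts over all non-empty signatures sum to
#' the union size.
#'
#' @param pathways List of 2 to `max_sets` [pathway()] objects.
#' @param max_sets Maximum number of sets (default 6; region count grows as
#'   `2^n - 1`).
#' @return Named integer vector: signature (pathway keys joined by `&`) ->
#'   gene count; only non-empty regions are reported.
#' @export
overlap_regions <- function(pathways, max_sets = 6L) {
  n <- length(pathways)
  if (n < 2L) abort_validation("overlap_regions requires at least two pathways")
  if (n > max_sets) {
    abort_limit(sprintf("overlap_regions supports at most %d sets (got %d)",
                        max_sets, n))
  }
  keys <- pathway_key(pathways)
  all_genes <- sort(unique(unlist(lapply(pathways, `[[`, "genes"),
                                  use.names = FALSE)))
  if (length(all_genes) == 0L) return(stats::setNames(integer(), character()))
  membership <- vapply(pathways, function(p) all_genes %in% p$genes,
                       logical(length(all_genes)))
  membership <- matrix(membership, nrow = length(all_genes))
  signature <- apply(membership, 1L, function(row) paste(keys[row], collapse = "&"))
  counts <- table(signature)
  stats::setNames(as.integer(counts), names(counts))
}

#' Average-linkage hierarchical clustering of pathways
#'
#' Agglomerative clustering on the distance `1 - overlap_coefficient`
#' between gene sets, with average (UPGMA) linkage. Among equal-distance
#' candidate merges the pair whose member keys are lexicographically
#' smallest is merged first, making the tree bit-reproducible.
#'
#' @param pathways List of at least two [pathway()] objects with distinct
#'   keys.
#' @return An object of class `hclust` (method `"average"`), with pathway
#'   keys as labels; usable with [stats::cophenetic()],
#'   [stats::cutree()], [ape::as.phylo()], etc.
#' @export
cluster_dendrogram <- function(pathways) {
  if (length(pathways) < 2L) {
    abort_validation("cluster_dendrogram requires at least two pathways")
  }
  keys <- pathway_key(pathways)
  if (anyDuplicated(keys)) {
    abort_validation("pathways must have distinct (resource, pathway_id)")
  }
  ord <- order(keys)
  pathways <- pathways[ord]
  keys <- keys[ord]
  n <- length(pathways)
  d <- matrix(0, n, n)
  suppressWarnings(
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <-
          1 - overlap_coefficient(pathways[[i]]$genes, pathways[[j]]$genes)
      }
    }
  )
  average_linkage_hclust(d, keys)
}

# Naive O(n^3) UPGMA agglomeration with deterministic tie-breaking: among
# minimum-distance cluster pairs pick the one whose sorted member-label
# vectors are lexicographically smallest. Returns a stats::hclust object.
average_linkage_hclust <- function(d, labels) {
  n <- nrow(d)
  active <- seq_len(n)
  # cluster bookkeeping: id < 0 => singleton -i (hclust convention),
  # id > 0 => merge row
  node_of <- -seq_len(n)
  size <- rep(1L, n)
  members <- lapply(labels, identity)
  dist_cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    best_d <- Inf
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        dv <- dist_cur[a, b]
        if (dv < best_d - 1e-12) {
          best_d <- dv
          best <- c(a, b)
        } else if (abs(dv - best_d) <= 1e-12 && !is.null(best)) {
          cand <- tie_key(members[[a]], members[[b]])
          cur <- tie_key(members[[best[1]]], members[[best[2]]])
          if (cand < cur) best <- c(a, b)
        }
      }
    }
    a <- best[1]; b <- best[2]
    merge[step, ] <- sort_merge_pair(node_of[a], node_of[b])
    height[step] <- best_d
    # average linkage update against every other cluster
    k_rest <- setdiff(seq_len(k), c(a, b))
    new_row <- vapply(k_rest, function(x) {
      (size[a] * dist_cur[a, x] + size[b] * dist_cur[b, x]) / (size[a] + size[b])
    }, numeric(1))
    new_members <- sort(c(members[[a]], members[[b]]))
    new_size <- size[a] + size[b]
    dist_cur <- dist_cur[k_rest, k_rest, drop = FALSE]
    dist_cur <- rbind(cbind(dist_cur, new_row), c(new_row, 0))
    members <- c(members[k_rest], list(new_members))
    size <- c(size[k_rest], new_size)
    node_of <- c(node_of[k_rest], step)
    active <- seq_len(k - 1L)
  }
  structure(
    list(
      merge = merge,
      height = height,
      order = hclust_leaf_order(merge, n),
      labels = labels,
      method = "average",
      call = match.call(),
      dist.method = "1 - overlap coefficient"
    ),
    class = "hclust"
  )
}

tie_key <- function(m1, m2) {
  paste(sort(c(paste(sort(m1), collapse = "|"), paste(sort(m2), collapse = "|"))),
        collapse = "||")
}

# hclust convention: singletons as negative indices, earlier merges first
sort_merge_pair <- function(x, y) {
  if (x < 0 && y < 0) sort(c(x, y), decreasing = TRUE)
  else if (x < 0) c(x, y)
  else if (y < 0) c(y, x)
  else sort(c(x, y))
}

hclust_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' Assign unassigned pathways to their closest module
#'
#' Each unassigned pathway joins the module containing its nearest assigned
#' leaf by cophenetic distance on the dendrogram; ties are broken toward
#' the module with the smallest id. Pathways remain unassigned when no
#' module exists.
#'
#' @param partition A `module_partition` from [detect_modules()].
#' @param dendrogram An `hclust` object over the same pathway keys (from
#'   [cluster_dendrogram()]).
#' @return A new `module_partition` with (possibly) enlarged modules.
#' @export
assign_to_closest_module <- function(partition, dendrogram) {
  stopifnot(inherits(partition, "module_partition"), inherits(dendrogram, "hclust"))
  all_keys <- sort(c(unlist(partition$modules, use.names = FALSE),
                     partition$unassigned))
  if (!setequal(all_keys, dendrogram$labels)) {
    abort_validation("partition and dendrogram must cover the same pathways")
  }
  if (length(partition$modules) == 0L || length(partition$unassigned) == 0L) {
    return(partition)
  }
  coph <- as.matrix(stats::cophenetic(dendrogram))
  module_of <- stats::setNames(
    rep(names(partition$modules), lengths(partition$modules)),
    unlist(partition$modules, use.names = FALSE)
  )
  assigned_keys <- names(module_of)
  modules <- partition$modules
  module_ids <- names(modules)
  for (key in partition$unassigned) {
    dists <- coph[key, assigned_keys]
    nearest <- assigned_keys[dists == min(dists)]
    cand_modules <- sort(unique(module_of[nearest]))
    target <- cand_modules[order(match(cand_modules, module_ids))][1]
    modules[[target]] <- sort(c(modules[[target]], key))
  }
  structure(
    list(modules = modules, unassigned = character()),
    class = "module_partition"
  )
}

#' Export a network as an edge-list TSV
#'
#' Columns `source`, `target`, `weight`, sorted by source then target.
#'
#' @param net A `pathway_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  el <- network_edges(net)
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Edge list of a pathway network
#'
#' @param net A `pathway_network`.
#' @return Data.frame with `source`, `target`, `weight`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "pathway_network"))
  if (igraph::ecount(net$graph) == 0L) {
    return(data.frame(source = character(), target = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  el <- igraph::as_edgelist(net$graph)
  df <- data.frame(
    source = pmin(el[, 1], el[, 2]),
    target = pmax(el[, 1], el[, 2]),
    weight = igraph::E(net$graph)$weight,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$source, df$target), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a network as graph-viewer JSON
#'
#' Nodes (key, resource, pathway_id, name, gene count) and weighted edges.
#'
#' @param net A `pathway_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  nodes <- lapply(net$pathways, function(p) {
    list(key = paste0(p$resource, ":", p$pathway_id), resource = p$resource,
         pathway_id = p$pathway_id, name = p$name, n_genes = length(p$genes))
  })
  el <- network_edges(net)
  edges <- lapply(seq_len(nrow(el)), function(i) {
    list(source = el$source[i], target = el$target[i], weight = el$weight[i])
  })
  jsonlite::write_json(
    list(threshold = net$threshold, nodes = unname(nodes), edges = edges),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from the merge heights via [ape::as.phylo()].
#' Colons in pathway keys are replaced by dashes, since `:` is reserved in
#' Newick syntax.
#'
#' @param dendrogram An `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  phy <- ape::as.phylo(dendrogram)
  phy$tip.label <- gsub(":", "-", phy$tip.label, fixed = TRUE)
  ape::write.tree(phy, file = path)
  invisible(path)
}
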