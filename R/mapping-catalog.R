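# Curation core: a catalog of typed pathway mappings.
#
# Two relation types: equivalentTo (undirected; both pathways describe the
# same biological process) and isPartOf (directed; side 1 is the child
# sub-process of the side-2 parent). Both require at least one shared gene
# between the two gene sets — the only mechanically enforceable of the
# curation requirements (scope and biological context are human
# judgments). equivalentTo mappings are stored in canonical orientation
# (lexicographically smaller (resource, pathway_id) first) so lookups are
# order-independent.
#
# Community voting: each curator holds one vote (+1/-1, later votes
# replace earlier); a mapping with net vote sum strictly greater than the
# acceptance threshold (default 3) is automatically accepted. The
# proposer's proposal counts as a +1 vote.

#' Create an empty mapping catalog
#'
#' @param vote_threshold Net vote sum that must be strictly exceeded for
#'   automatic acceptance (default 3).
#' @return Object of class `mapping_catalog`.
#' @export
mapping_catalog <- function(vote_threshold = 3L) {
  structure(
    list(mappings = list(), vote_threshold = as.integer(vote_threshold)),
    class = "mapping_catalog"
  )
}

#' @export
print.mapping_catalog <- function(x, ...) {
  states <- vapply(x$mappings, `[[`, character(1), "state")
  cat(sprintf(
    "<mapping_catalog> %d mappings (%d accepted, %d proposed, %d rejected)\n",
    length(states), sum(states == "accepted"), sum(states == "proposed"),
    sum(states == "rejected")
  ))
  invisible(x)
}

pathway_ref <- function(p) {
  list(resource = p$resource, pathway_id = p$pathway_id, name = p$name)
}

# canonical orientation: equivalentTo sorted by (resource, pathway_id);
# isPartOf keeps child -> parent
orient_pair <- function(ref1, ref2, relation) {
  if (relation == "equivalentTo") {
    k1 <- paste(ref1$resource, ref1$pathway_id, sep = "\r")
    k2 <- paste(ref2$resource, ref2$pathway_id, sep = "\r")
    if (k2 < k1) return(list(ref2, ref1))
  }
  list(ref1, ref2)
}

mapping_key <- function(ref1, ref2, relation) {
  oriented <- orient_pair(ref1, ref2, relation)
  paste(relation,
        oriented[[1]]$resource, oriented[[1]]$pathway_id,
        oriented[[2]]$resource, oriented[[2]]$pathway_id,
        sep = "|")
}

recompute_state <- function(mapping, vote_threshold) {
  net <- sum(mapping$votes)
  if (isTRUE(mapping$consensus_accepted) || net > vote_threshold) {
    "accepted"
  } else if (net < -vote_threshold) {
    "rejected"
  } else {
    "proposed"
  }
}

#' Propose a pathway mapping
#'
#' Validates and records a typed mapping between two pathways. Both
#' relation types require at least one shared gene; self-mappings are
#' rejected. Intra-database mappings (same resource, different pathway_id)
#' are permitted. The proposer's proposal counts as a +1 vote. Proposing
#' an already-present mapping leaves the catalog unchanged.
#'
#' @param catalog A [mapping_catalog()].
#' @param p1,p2 [pathway()] objects. For `isPartOf`, `p1` is the child and
#'   `p2` the parent.
#' @param relation `"equivalentTo"` or `"isPartOf"`.
#' @param proposer Curator identifier (non-empty string).
#' @return The updated catalog.
#' @export
propose_mapping <- function(catalog, p1, p2, relation, proposer) {
  stopifnot(inherits(catalog, "mapping_catalog"),
            inherits(p1, "pathway"), inherits(p2, "pathway"))
  if (!relation %in% RELATION_TYPES) {
    abort_validation(sprintf("unknown relation '%s'", relation))
  }
  if (!is.character(proposer) || length(proposer) != 1L || !nzchar(proposer)) {
    abort_validation("proposer must be a non-empty curator id")
  }
  if (p1$resource == p2$resource && p1$pathway_id == p2$pathway_id) {
    abort_validation("cannot map a pathway to itself")
  }
  if (length(intersect(p1$genes, p2$genes)) < 1L) {
    abort_validation(sprintf(
      "mapping requires at least one shared gene (%s:%s and %s:%s share none)",
      p1$resource, p1$pathway_id, p2$resource, p2$pathway_id
    ))
  }
  key <- mapping_key(pathway_ref(p1), pathway_ref(p2), relation)
  if (!is.null(catalog$mappings[[key]])) {
    return(catalog)
  }
  oriented <- orient_pair(pathway_ref(p1), pathway_ref(p2), relation)
  mapping <- list(
    record = list(
      resource_1 = oriented[[1]]$resource,
      pathway_id_1 = oriented[[1]]$pathway_id,
      name_1 = oriented[[1]]$name,
      relation = relation,
      resource_2 = oriented[[2]]$resource,
      pathway_id_2 = oriented[[2]]$pathway_id,
      name_2 = oriented[[2]]$name
    ),
    proposer = proposer,
    votes = stats::setNames(1L, proposer),
    consensus_accepted = FALSE,
    state = "proposed"
  )
  mapping$state <- recompute_state(mapping, catalog$vote_threshold)
  catalog$mappings[[key]] <- mapping
  catalog
}

#' Retrieve a mapping from the catalog
#'
#' Lookup is orientation-independent for `equivalentTo`.
#'
#' @param catalog A [mapping_catalog()].
#' @param p1,p2 [pathway()] objects (or lists with `resource`,
#'   `pathway_id` fields).
#' @param relation `"equivalentTo"` or `"isPartOf"`.
#' @return The mapping (list with `record`, `proposer`, `votes`, `state`)
#'   or `NULL` if absent.
#' @export
get_mapping <- function(catalog, p1, p2, relation) {
  key <- mapping_key(
    list(resource = p1$resource, pathway_id = p1$pathway_id),
    list(resource = p2$resource, pathway_id = p2$pathway_id),
    relation
  )
  catalog$mappings[[key]]
}

#' Cast or replace a curator's vote on a mapping
#'
#' Each curator holds exactly one vote; voting again replaces the earlier
#' vote. The mapping state is recomputed: accepted iff the net vote sum
#' strictly exceeds the catalog's threshold (default 3); rejected iff it
#' falls strictly below the negated threshold.
#'
#' @inheritParams get_mapping
#' @param curator Curator identifier.
#' @param direction `+1` (agree) or `-1` (disagree).
#' @return The updated catalog.
#' @export
cast_vote <- function(catalog, p1, p2, relation, curator, direction) {
  stopifnot(inherits(catalog, "mapping_catalog"))
  if (!direction %in% c(1L, -1L)) {
    abort_validation("vote direction must be +1 or -1")
  }
  key <- mapping_key(
    list(resource = p1$resource, pathway_id = p1$pathway_id),
    list(resource = p2$resource, pathway_id = p2$pathway_id),
    relation
  )
  mapping <- catalog$mappings[[key]]
  if (is.null(mapping)) {
    abort_lookup(sprintf("no such mapping in catalog: %s", key))
  }
  mapping$votes[curator] <- as.integer(direction)
  mapping$state <- recompute_state(mapping, catalog$vote_threshold)
  catalog$mappings[[key]] <- mapping
  catalog
}

#' All mapping records in a catalog as a data.frame
#'
#' @param catalog A [mapping_catalog()].
#' @param state Optional filter: keep only mappings in this state (e.g.
#'   `"accepted"`).
#' @return Data.frame with the seven mapping-TSV columns plus `proposer`,
#'   `net_votes`, `state`, sorted by key for reproducibility.
#' @export
catalog_records <- function(catalog, state = NULL) {
  stopifnot(inherits(catalog, "mapping_catalog"))
  maps <- catalog$mappings
  if (length(maps) > 0L) maps <- maps[order(names(maps))]
  if (!is.null(state)) {
    maps <- Filter(function(m) m$state %in% state, maps)
  }
  if (length(maps) == 0L) {
    out <- data.frame(matrix(character(), 0, 7,
                             dimnames = list(NULL, MAPPING_TSV_COLUMNS)),
                      stringsAsFactors = FALSE)
    out$proposer <- character()
    out$net_votes <- integer()
    out$state <- character()
    return(out)
  }
  rows <- lapply(maps, function(m) {
    cbind(as.data.frame(m$record, stringsAsFactors = FALSE),
          data.frame(proposer = m$proposer, net_votes = sum(m$votes),
                     state = m$state, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dump a catalog (records, votes, states) to JSON
#'
#' @param catalog A [mapping_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(catalog, path) {
  maps <- catalog$mappings[order(names(catalog$mappings))]
  out <- lapply(maps, function(m) {
    list(record = m$record, proposer = m$proposer,
         votes = as.list(m$votes), net_votes = sum(m$votes),
         state = m$state)
  })
  jsonlite::write_json(
    list(vote_threshold = catalog$vote_threshold, mappings = unname(out)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Suggest candidate mappings for a pathway
#'
#' Scores every candidate pathway on two independent metrics — content
#' similarity (Szymkiewicz-Simpson [overlap_coefficient()] on gene sets)
#' and lexical similarity (normalized Levenshtein on names) — and ranks
#' them. The default combiner ranks by the larger of the two scores so a
#' candidate strong on either axis surfaces; `content`/`lexical` rank on a
#' single metric. Ties break by (resource, pathway_id). Candidates flagged
#' `imported` (pathways a database copied from another resource) and the
#' query pathway itself are skipped.
#'
#' @param p A [pathway()].
#' @param candidate_dbs A [pathway_database()] or list of them.
#' @param top_n Number of suggestions returned (default 5).
#' @param combiner `"max"`, `"content"`, or `"lexical"`.
#' @return Data.frame with `resource`, `pathway_id`, `name`,
#'   `content_similarity`, `lexical_similarity`, `score`, `rank`.
#' @export
suggest_mappings <- function(p, candidate_dbs, top_n = 5L,
                             combiner = c("max", "content", "lexical")) {
  combiner <- match.arg(combiner)
  stopifnot(inherits(p, "pathway"))
  candidate_dbs <- as_database_list(candidate_dbs)
  cands <- unlist(lapply(candidate_dbs, `[[`, "pathways"), recursive = FALSE,
                  use.names = FALSE)
  cands <- Filter(function(q) {
    !(q$resource == p$resource && q$pathway_id == p$pathway_id) &&
      !isTRUE(q$imported)
  }, cands)
  if (length(cands) == 0L) {
    abort_validation("no candidate pathways to score")
  }
  content <- vapply(cands, function(q) {
    suppressWarnings(overlap_coefficient(p$genes, q$genes))
  }, numeric(1))
  # single adist call over all candidate names (much faster than pairwise)
  a <- canonical_name(p$name)
  cn <- vapply(cands, function(q) canonical_name(q$name), character(1))
  d <- drop(utils::adist(a, cn))
  lexical <- 1 - d / pmax(nchar(a), nchar(cn), 1L)
  score <- switch(combiner,
    max = pmax(content, lexical),
    content = content,
    lexical = lexical
  )
  out <- data.frame(
    resource = vapply(cands, `[[`, character(1), "resource"),
    pathway_id = vapply(cands, `[[`, character(1), "pathway_id"),
    name = vapply(cands, `[[`, character(1), "name"),
    content_similarity = content,
    lexical_similarity = lexical,
    score = score,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$resource, out$pathway_id), , drop = FALSE]
  out <- utils::head(out, top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build a catalog from mapping records and their databases
#'
#' Resolves each record's pathways in the supplied databases and proposes
#' the mapping (validating the shared-gene requirement). Records whose
#' pathways cannot be found, or that fail validation, are skipped with a
#' warning.
#'
#' @param records Data.frame in the seven-column mapping-TSV layout.
#' @param dbs A [pathway_database()] or list of them.
#' @param proposer Curator id recorded for every imported mapping.
#' @param vote_threshold Acceptance threshold for the new catalog.
#' @return A [mapping_catalog()].
#' @export
catalog_from_records <- function(records, dbs, proposer = "import",
                                 vote_threshold = 3L) {
  dbs <- as_database_list(dbs)
  by_resource <- stats::setNames(dbs, vapply(dbs, `[[`, character(1), "resource"))
  lookup <- function(resource, id) {
    db <- by_resource[[resource]]
    if (is.null(db)) return(NULL)
    db$pathways[[id]]
  }
  catalog <- mapping_catalog(vote_threshold)
  for (i in seq_len(nrow(records))) {
    p1 <- lookup(records$resource_1[i], records$pathway_id_1[i])
    p2 <- lookup(records$resource_2[i], records$pathway_id_2[i])
    if (is.null(p1) || is.null(p2)) {
      warn_pathmapr(sprintf(
        "skipping mapping %d: pathway not found in supplied databases", i
      ))
      next
    }
    catalog <- tryCatch(
      propose_mapping(catalog, p1, p2, records$relation[i], proposer),
      pathmapr_validation_error = function(e) {
        warn_pathmapr(sprintf("skipping mapping %d: %s", i, conditionMessage(e)))
        catalog
      }
    )
  }
  catalog
}

#' Merge curator catalogs into a consensus catalog
#'
#' A mapping proposed identically (same oriented pair and relation) in a
#' majority of the input catalogs is accepted in the merged catalog.
#' Mappings seen only in a minority are carried over as proposed and
#' flagged for review; pairs assigned different relation types across
#' catalogs are always flagged as conflicts and never auto-resolved (they
#' are excluded from the merged catalog).
#'
#' @param catalogs List of at least two [mapping_catalog()] objects.
#' @return List with `catalog` (the merged [mapping_catalog()]) and
#'   `conflicts` (data.frame with `type` in `minority`/`relation_conflict`,
#'   the pair columns, and `n_catalogs` support count).
#' @export
merge_consensus <- function(catalogs) {
  if (length(catalogs) < 2L ||
      !all(vapply(catalogs, inherits, logical(1), "mapping_catalog"))) {
    abort_validation("merge_consensus requires at least two mapping catalogs")
  }
  majority <- floor(length(catalogs) / 2) + 1L
  all_keys <- sort(unique(unlist(lapply(catalogs, function(ct) names(ct$mappings)),
                                 use.names = FALSE)))
  support <- vapply(all_keys, function(k) {
    sum(vapply(catalogs, function(ct) !is.null(ct$mappings[[k]]), logical(1)))
  }, integer(1))

  # pair signature ignoring relation (and orientation) to detect
  # relation-type conflicts
  pair_sig <- vapply(all_keys, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sides <- sort(c(paste(parts[2], parts[3], sep = ":"),
                    paste(parts[4], parts[5], sep = ":")))
    paste(sides, collapse = "~")
  }, character(1))
  relation_of <- vapply(strsplit(all_keys, "|", fixed = TRUE), `[[`,
                        character(1), 1L)
  conflict_pairs <- names(which(
    vapply(split(relation_of, pair_sig), function(r) length(unique(r)) > 1L,
           logical(1))
  ))

  merged <- mapping_catalog(vote_threshold = catalogs[[1]]$vote_threshold)
  conflicts <- list()
  for (i in seq_along(all_keys)) {
    k <- all_keys[i]
    donor <- NULL
    for (ct in catalogs) {
      if (!is.null(ct$mappings[[k]])) { donor <- ct$mappings[[k]]; break }
    }
    rec <- donor$record
    row <- data.frame(
      resource_1 = rec$resource_1, pathway_id_1 = rec$pathway_id_1,
      relation = rec$relation,
      resource_2 = rec$resource_2, pathway_id_2 = rec$pathway_id_2,
      n_catalogs = support[i], stringsAsFactors = FALSE
    )
    if (pair_sig[i] %in% conflict_pairs) {
      row$type <- "relation_conflict"
      conflicts[[length(conflicts) + 1L]] <- row
      next
    }
    m <- donor
    m$consensus_accepted <- support[i] >= majority
    m$state <- recompute_state(m, merged$vote_threshold)
    merged$mappings[[k]] <- m
    if (support[i] < majority) {
      row$type <- "minority"
      conflicts[[length(conflicts) + 1L]] <- row
    }
  }
  conflict_df <- if (length(conflicts)) {
    out <- do.call(rbind, conflicts)
    out <- out[order(out$type, out$relation, out$resource_1, out$pathway_id_1,
                     out$resource_2, out$pathway_id_2), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(resource_1 = character(), pathway_id_1 = character(),
               relation = character(), resource_2 = character(),
               pathway_id_2 = character(), n_catalogs = integer(),
               type = character(), stringsAsFactors = FALSE)
  }
  list(catalog = merged, conflicts = conflict_df)
}

#' Reasoning over pathway mappings: closure of accepted relations
#'
#' Computes the symmetric closure of `equivalentTo`, the transitive
#' closure of `isPartOf`, and the substitution rule (if A equivalentTo B
#' and B isPartOf C, then A isPartOf C, on either side). Derived relations
#' are marked `inferred`. A cycle in the `isPartOf` closure (a pathway
#' reachable as its own ancestor) is a consistency error naming the cycle.
#'
#' @param catalog A [mapping_catalog()]; only accepted mappings are used.
#' @return Data.frame with `resource_1`, `pathway_id_1`, `relation`,
#'   `resource_2`, `pathway_id_2`, `inferred`.
#' @export
infer_hierarchy <- function(catalog) {
  stopifnot(inherits(catalog, "mapping_catalog"))
  recs <- catalog_records(catalog, state = "accepted")
  infer_hierarchy_records(
    recs[, c("resource_1", "pathway_id_1", "relation", "resource_2",
             "pathway_id_2")]
  )
}

#' Closure of a raw relation set
#'
#' The reasoning core behind [infer_hierarchy()], operating directly on a
#' relation data.frame; idempotent (closing an already-closed set adds
#' nothing).
#'
#' @param records Data.frame with columns `resource_1`, `pathway_id_1`,
#'   `relation`, `resource_2`, `pathway_id_2`.
#' @return Data.frame as in [infer_hierarchy()], sorted; `inferred` marks
#'   relations not present in the input (with `equivalentTo` compared in
#'   canonical orientation).
#' @export
infer_hierarchy_records <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("resource_1", "pathway_id_1", "relation", "resource_2",
              "pathway_id_2")
  stopifnot(all(needed %in% names(records)))
  records <- unique(records[, needed, drop = FALSE])
  key1 <- paste(records$resource_1, records$pathway_id_1, sep = ":")
  key2 <- paste(records$resource_2, records$pathway_id_2, sep = ":")
  nodes <- sort(unique(c(key1, key2)))
  if (length(nodes) == 0L) {
    return(data.frame(resource_1 = character(), pathway_id_1 = character(),
                      relation = character(), resource_2 = character(),
                      pathway_id_2 = character(), inferred = logical(),
                      stringsAsFactors = FALSE))
  }
  eq <- records$relation == "equivalentTo"

  # equivalence classes via union-find
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in which(eq)) {
    ra <- find(key1[i]); rb <- find(key2[i])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  class_of <- vapply(nodes, find, character(1))
  classes <- split(nodes, class_of)

  # class-level isPartOf reachability (Warshall)
  cls <- names(classes)
  nc <- length(cls)
  reach <- matrix(FALSE, nc, nc, dimnames = list(cls, cls))
  for (i in which(!eq)) {
    a <- class_of[[key1[i]]]
    b <- class_of[[key2[i]]]
    reach[a, b] <- TRUE
  }
  for (k in seq_len(nc)) {
    reach <- reach | (reach[, k] %o% reach[k, ])
  }
  cyclic <- which(diag(reach))
  if (length(cyclic) > 0L) {
    members <- sort(unlist(classes[cyclic], use.names = FALSE))
    abort_consistency(sprintf(
      "isPartOf cycle detected involving: %s", paste(members, collapse = " -> ")
    ))
  }

  split_key <- function(k) {
    pos <- regexpr(":", k, fixed = TRUE)
    c(substr(k, 1L, pos - 1L), substr(k, pos + 1L, nchar(k)))
  }
  out <- list()
  add <- function(a, b, relation) {
    sa <- split_key(a); sb <- split_key(b)
    out[[length(out) + 1L]] <<- data.frame(
      resource_1 = sa[1], pathway_id_1 = sa[2], relation = relation,
      resource_2 = sb[1], pathway_id_2 = sb[2], stringsAsFactors = FALSE
    )
  }
  # symmetric closure of equivalentTo: all ordered pairs within a class
  for (cl in classes) {
    if (length(cl) < 2L) next
    for (a in cl) for (b in cl) if (a != b) add(a, b, "equivalentTo")
  }
  # isPartOf closure expanded back to pathway level through the classes
  for (a in cls) {
    for (b in cls) {
      if (reach[a, b]) {
        for (x in classes[[a]]) for (y in classes[[b]]) add(x, y, "isPartOf")
      }
    }
  }
  res <- unique(do.call(rbind, c(out, list(
    data.frame(resource_1 = character(), pathway_id_1 = character(),
               relation = character(), resource_2 = character(),
               pathway_id_2 = character(), stringsAsFactors = FALSE)
  ))))

  in_key <- canonical_relation_key(records)
  res$inferred <- !(canonical_relation_key(res) %in% in_key)
  res <- res[order(res$relation, res$resource_1, res$pathway_id_1,
                   res$resource_2, res$pathway_id_2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

canonical_relation_key <- function(df) {
  k1 <- paste(df$resource_1, df$pathway_id_1, sep = ":")
  k2 <- paste(df$resource_2, df$pathway_id_2, sep = ":")
  eq <- df$relation == "equivalentTo"
  a <- ifelse(eq, pmin(k1, k2), k1)
  b <- ifelse(eq, pmax(k1, k2), k2)
  paste(df$relation, a, b, sep = "|")
}

#' Summarize a mapping catalog against its databases
#'
#' Counts accepted mappings per (unordered) database pair and relation
#' type, and the fraction of each database's pathways with no accepted
#' mapping.
#'
#' @param catalog A [mapping_catalog()].
#' @param dbs List of [pathway_database()] objects.
#' @return List with `pair_counts` (data.frame `resource_a`, `resource_b`,
#'   `relation`, `n`) and `unmapped` (data.frame `resource`, `n_pathways`,
#'   `n_unmapped`, `unmapped_fraction`).
#' @export
catalog_summary <- function(catalog, dbs) {
  stopifnot(inherits(catalog, "mapping_catalog"))
  dbs <- as_database_list(dbs)
  recs <- catalog_records(catalog, state = "accepted")
  if (nrow(recs) > 0L) {
    ra <- pmin(recs$resource_1, recs$resource_2)
    rb <- pmax(recs$resource_1, recs$resource_2)
    tab <- stats::aggregate(
      list(n = seq_len(nrow(recs))),
      by = list(resource_a = ra, resource_b = rb, relation = recs$relation),
      FUN = length
    )
    tab <- tab[order(tab$resource_a, tab$resource_b, tab$relation), ,
               drop = FALSE]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(resource_a = character(), resource_b = character(),
                      relation = character(), n = integer(),
                      stringsAsFactors = FALSE)
  }
  mapped_keys <- unique(c(
    paste(recs$resource_1, recs$pathway_id_1, sep = ":"),
    paste(recs$resource_2, recs$pathway_id_2, sep = ":")
  ))
  unmapped <- do.call(rbind, lapply(dbs, function(db) {
    keys <- paste(db$resource, names(db$pathways), sep = ":")
    n_un <- sum(!keys %in% mapped_keys)
    data.frame(
      resource = db$resource,
      n_pathways = length(keys),
      n_unmapped = n_un,
      unmapped_fraction = if (length(keys)) n_un / length(keys) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(unmapped) <- NULL
  list(pair_counts = tab, unmapped = unmapped)
}

#' Export a catalog's records as a mapping TSV
#'
#' Writes the seven-column mapping TSV dialect of [write_mapping_tsv()],
#' optionally restricted to accepted mappings — the distribution format of
#' the curated catalog.
#'
#' @param catalog A [mapping_catalog()].
#' @param path Output file path.
#' @param accepted_only Write only accepted mappings (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path, accepted_only = TRUE) {
  recs <- catalog_records(catalog,
                          state = if (accepted_only) "accepted" else NULL)
  write_mapping_tsv(recs[, MAPPING_TSV_COLUMNS, drop = FALSE], path)
}
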