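# Deterministic synthetic multi-database pathway universes with planted
# ground truth, used to benchmark mapping suggestion, enrichment and
# network analysis without depending on any external database release.
#
# One reference database is drawn first; each further database receives
# noisy copies of a fraction of the reference pathways (planted
# equivalentTo pairs) plus fresh pathways of its own. Noise is an
# independent per-gene Bernoulli swap (drop + replacement from the
# universe, preserving set size) and a fixed number of random
# single-character edits to the copied name. Optional hierarchy levels
# plant isPartOf parents as unions of their children plus extra genes, so
# child gene sets are strict subsets of their parents.
#
# All randomness flows from the single integer seed in the spec; global
# RNG state is left untouched.

#' Specification for a synthetic pathway universe
#'
#' @param n_genes Universe size (synthetic symbols `G000001`, ...).
#' @param n_databases Number of databases (first is the reference).
#' @param pathways_per_db Base pathways per database.
#' @param size_range Length-2 integer vector: min/max pathway gene-set
#'   size (uniformly drawn).
#' @param fraction_equivalent Fraction of each non-reference database's
#'   pathways planted as noisy copies of reference pathways.
#' @param gene_noise_rate Per-gene probability that a copied gene is
#'   swapped for a random universe gene.
#' @param name_noise_edits Number of random character edits applied to
#'   copied pathway names.
#' @param hierarchy_depth Number of hierarchy levels (1 = flat; each extra
#'   level adds parents that union pairs of the previous level).
#' @param seed Integer seed; fully determines the output.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_databases = 3L,
                           pathways_per_db = 100L, size_range = c(10L, 80L),
                           fraction_equivalent = 0.3, gene_noise_rate = 0,
                           name_noise_edits = 0L, hierarchy_depth = 1L,
                           seed = 1L) {
  fr <- c(fraction_equivalent, gene_noise_rate)
  if (any(fr < 0 | fr > 1)) {
    abort_validation("fractions must lie in [0, 1]")
  }
  if (length(size_range) != 2L || size_range[1] < 1L ||
      size_range[2] < size_range[1]) {
    abort_validation("size_range must be c(min, max) with 1 <= min <= max")
  }
  if (size_range[2] > n_genes) {
    abort_validation("maximum pathway size exceeds the universe size")
  }
  if (n_databases < 1L || pathways_per_db < 1L || hierarchy_depth < 1L) {
    abort_validation("counts must be positive")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_databases = as.integer(n_databases),
      pathways_per_db = as.integer(pathways_per_db),
      size_range = as.integer(size_range),
      fraction_equivalent = fraction_equivalent,
      gene_noise_rate = gene_noise_rate,
      name_noise_edits = as.integer(name_noise_edits),
      hierarchy_depth = as.integer(hierarchy_depth),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

NAME_VOCAB <- c(
  "apoptosis", "autophagy", "mitophagy", "glycolysis", "proteolysis",
  "endocytosis", "exocytosis", "signaling", "transport", "biosynthesis",
  "degradation", "regulation", "activation", "repair", "replication",
  "transcription", "translation", "phosphorylation", "ubiquitination",
  "oxidation", "lysosomal", "mitochondrial", "nuclear", "cytosolic",
  "membrane", "vesicle", "receptor", "kinase", "channel", "cascade",
  "stress", "immune", "metabolic", "neuronal", "synaptic", "hormonal",
  "lipid", "amino-acid", "nucleotide", "calcium"
)

random_pathway_name <- function() {
  paste(sample(NAME_VOCAB, 3L, replace = FALSE), collapse = " ")
}

perturb_name <- function(name, n_edits) {
  alphabet <- letters
  for (i in seq_len(n_edits)) {
    op <- sample(c("sub", "ins", "del"), 1L)
    chars <- strsplit(name, "", fixed = TRUE)[[1]]
    n <- length(chars)
    if (op == "sub" && n > 0L) {
      pos <- sample.int(n, 1L)
      chars[pos] <- sample(alphabet, 1L)
    } else if (op == "ins") {
      pos <- sample.int(n + 1L, 1L)
      chars <- append(chars, sample(alphabet, 1L), after = pos - 1L)
    } else if (n > 1L) {
      chars <- chars[-sample.int(n, 1L)]
    }
    name <- paste(chars, collapse = "")
  }
  name
}

perturb_genes <- function(genes, universe, rate) {
  if (rate <= 0) return(genes)
  swap <- stats::runif(length(genes)) < rate
  if (!any(swap)) return(genes)
  kept <- genes[!swap]
  pool <- setdiff(universe, genes)
  replacement <- sample(pool, min(sum(swap), length(pool)))
  sort(unique(c(kept, replacement)))
}

#' Generate a synthetic multi-database pathway universe
#'
#' @param spec A [synthetic_spec()].
#' @return List with `databases` (list of [pathway_database()]),
#'   `universe` (a [gene_universe()]), and `truth` (data.frame of planted
#'   mapping records in the seven-column TSV layout, `equivalentTo` for
#'   planted copies and `isPartOf` for planted hierarchy links).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  genes_all <- sprintf("G%06d", seq_len(spec$n_genes))
  universe <- gene_universe(genes_all, label = "synthetic")
  n_eq <- round(spec$fraction_equivalent * spec$pathways_per_db)

  databases <- vector("list", spec$n_databases)
  truth <- list()

  draw_pathway <- function(resource, id, name = random_pathway_name()) {
    size <- sample(spec$size_range[1]:spec$size_range[2], 1L)
    pathway(resource, id, name, sample(genes_all, size))
  }

  ref <- NULL
  for (d in seq_len(spec$n_databases)) {
    resource <- sprintf("DB%d", d)
    ps <- vector("list", spec$pathways_per_db)
    for (i in seq_len(spec$pathways_per_db)) {
      id <- sprintf("PW%04d", i)
      if (d > 1L && i <= n_eq) {
        src <- ref$pathways[[i]]
        ps[[i]] <- pathway(
          resource, id,
          perturb_name(src$name, spec$name_noise_edits),
          perturb_genes(src$genes, genes_all, spec$gene_noise_rate)
        )
        truth[[length(truth) + 1L]] <- data.frame(
          resource_1 = src$resource, pathway_id_1 = src$pathway_id,
          name_1 = src$name, relation = "equivalentTo",
          resource_2 = resource, pathway_id_2 = id,
          name_2 = ps[[i]]$name, stringsAsFactors = FALSE
        )
      } else {
        ps[[i]] <- draw_pathway(resource, id)
      }
    }
    # plant hierarchy levels: parents union pairs of the previous level
    if (spec$hierarchy_depth > 1L) {
      level <- ps
      for (lev in 2:spec$hierarchy_depth) {
        n_parents <- length(level) %/% 2L
        if (n_parents == 0L) break
        parents <- vector("list", n_parents)
        for (k in seq_len(n_parents)) {
          children <- level[(2L * k - 1L):(2L * k)]
          id <- sprintf("PWL%d_%04d", lev, k)
          extra <- sample(genes_all, max(1L, spec$size_range[1] %/% 2L))
          parents[[k]] <- pathway(
            resource, id, random_pathway_name(),
            unique(c(unlist(lapply(children, `[[`, "genes")), extra))
          )
          for (ch in children) {
            truth[[length(truth) + 1L]] <- data.frame(
              resource_1 = resource, pathway_id_1 = ch$pathway_id,
              name_1 = ch$name, relation = "isPartOf",
              resource_2 = resource, pathway_id_2 = id,
              name_2 = parents[[k]]$name, stringsAsFactors = FALSE
            )
          }
        }
        ps <- c(ps, parents)
        level <- parents
      }
    }
    databases[[d]] <- pathway_database(
      resource, sprintf("synthetic-seed%d", spec$seed), ps
    )
    if (d == 1L) ref <- databases[[1L]]
  }

  truth_df <- if (length(truth)) {
    out <- do.call(rbind, truth)
    rownames(out) <- NULL
    out
  } else {
    data.frame(resource_1 = character(), pathway_id_1 = character(),
               name_1 = character(), relation = character(),
               resource_2 = character(), pathway_id_2 = character(),
               name_2 = character(), stringsAsFactors = FALSE)
  }
  list(databases = databases, universe = universe, truth = truth_df)
}

#' Top-k recovery of planted mapping partners
#'
#' Given per-pathway suggestion rankings and the planted ground truth,
#' computes the fraction of truth-involved pathways for which at least one
#' planted equivalent partner appears within the top `k` suggestions.
#' Partners are taken from the symmetric-transitive closure of the planted
#' `equivalentTo` pairs (two noisy copies of the same reference pathway
#' count as partners of each other), so a perfect suggester scores 1 even
#' when a pathway has several interchangeable planted partners.
#'
#' @param suggestions Named list: pathway key (`resource:pathway_id`) ->
#'   data.frame from [suggest_mappings()] (or a character vector of
#'   candidate keys in rank order).
#' @param truth Ground-truth data.frame as produced by
#'   [generate_synthetic()].
#' @param k Rank cutoff (default 1).
#' @return Fraction in `[0, 1]` (0 when the truth contains no
#'   `equivalentTo` pairs or `suggestions` is empty).
#' @export
score_recovery <- function(suggestions, truth, k = 1L) {
  eq <- truth[truth$relation == "equivalentTo", , drop = FALSE]
  if (nrow(eq) == 0L) return(0)
  key1 <- paste(eq$resource_1, eq$pathway_id_1, sep = ":")
  key2 <- paste(eq$resource_2, eq$pathway_id_2, sep = ":")
  nodes <- unique(c(key1, key2))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(key1)) {
    ra <- find(key1[i]); rb <- find(key2[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  class_of <- vapply(nodes, find, character(1))
  hits <- vapply(nodes, function(f) {
    partners <- setdiff(nodes[class_of == class_of[[f]]], f)
    s <- suggestions[[f]]
    if (is.null(s) || length(partners) == 0L) return(FALSE)
    keys <- if (is.data.frame(s)) {
      paste(s$resource, s$pathway_id, sep = ":")
    } else {
      as.character(s)
    }
    any(partners %in% utils::head(keys, k))
  }, logical(1))
  mean(hits)
}

#' Write a synthetic universe to disk
#'
#' One GMT file per database, the universe as a gene list, and the planted
#' truth as a mapping TSV — the same formats the readers in the package
#' consume.
#'
#' @param generated Output of [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_synthetic <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (db in generated$databases) {
    p <- file.path(dir, paste0(tolower(db$resource), ".gmt"))
    write_gmt(db, p)
    paths <- c(paths, p)
  }
  up <- file.path(dir, "universe.txt")
  writeLines(generated$universe$genes, up)
  tp <- file.path(dir, "truth_mappings.tsv")
  write_mapping_tsv(generated$truth, tp)
  invisible(c(paths, up, tp))
}
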