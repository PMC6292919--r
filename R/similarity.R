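# Pathway similarity metrics.
#
# Content similarity is the Szymkiewicz-Simpson overlap coefficient
# S(X,Y) = |X ∩ Y| / min(|X|, |Y|), chosen over Jaccard or Sørensen-Dice
# because it behaves well for sets of widely differing size and equals 1
# whenever one set contains the other, surfacing candidate hierarchical
# relationships. Lexical similarity is a Levenshtein edit distance on
# pathway names, normalized to [0,1] by the longer name's length.

#' Szymkiewicz-Simpson overlap coefficient between two gene sets
#'
#' Computes `|X ∩ Y| / min(|X|, |Y|)`. Symmetric; equals 1 for non-empty
#' sets iff one contains the other. The coefficient is undefined when
#' either set is empty; by convention 0 is returned with a warning, since
#' an empty pathway carries no evidence of similarity.
#'
#' @param x,y Character vectors (gene sets); duplicates are ignored.
#' @return A number in `[0, 1]`.
#' @examples
#' overlap_coefficient(c("A", "B"), c("A", "B", "C", "D"))  # containment: 1
#' overlap_coefficient(c("A", "B", "C"), c("B", "C", "D", "E"))  # 2/3
#' @export
overlap_coefficient <- function(x, y) {
  x <- unique(x)
  y <- unique(y)
  m <- min(length(x), length(y))
  if (m == 0L) {
    warn_pathmapr("overlap coefficient of an empty set is undefined; returning 0",
                  class = "pathmapr_empty_geneset_warning")
    return(0)
  }
  length(intersect(x, y)) / m
}

#' Jaccard index between two gene sets
#'
#' `|X ∩ Y| / |X ∪ Y|`; provided as an alternative content metric. Returns
#' 0 for two empty sets.
#'
#' @inheritParams overlap_coefficient
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(x, y) {
  x <- unique(x)
  y <- unique(y)
  u <- length(union(x, y))
  if (u == 0L) return(0)
  length(intersect(x, y)) / u
}

#' Sørensen-Dice coefficient between two gene sets
#'
#' `2 |X ∩ Y| / (|X| + |Y|)`; alternative content metric. Returns 0 when
#' both sets are empty.
#'
#' @inheritParams overlap_coefficient
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(x, y) {
  x <- unique(x)
  y <- unique(y)
  denom <- length(x) + length(y)
  if (denom == 0L) return(0)
  2 * length(intersect(x, y)) / denom
}

#' Levenshtein edit distance between two strings
#'
#' Minimum number of single-character insertions, deletions and
#' substitutions transforming `a` into `b`. Comparison is case-insensitive
#' after collapsing runs of whitespace, matching how pathway names are
#' compared throughout the package.
#'
#' @param a,b Single strings.
#' @param normalize_case Lowercase and collapse whitespace before comparing
#'   (default `TRUE`).
#' @return Non-negative integer.
#' @examples
#' levenshtein_distance("kitten", "sitting")  # 3
#' @export
levenshtein_distance <- function(a, b, normalize_case = TRUE) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (normalize_case) {
    a <- canonical_name(a)
    b <- canonical_name(b)
  }
  as.integer(utils::adist(a, b)[1, 1])
}

canonical_name <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

#' Normalized lexical similarity between two pathway names
#'
#' `1 - d / max(nchar(a), nchar(b))` where `d` is the case-insensitive
#' Levenshtein distance; bounded to `[0, 1]` and equal to 1 iff the names
#' match up to case and whitespace collapsing.
#'
#' @param name_a,name_b Pathway names (at least one non-empty).
#' @return A number in `[0, 1]`.
#' @examples
#' lexical_similarity("Mitophagy", "Mitophagy pathway")
#' @export
lexical_similarity <- function(name_a, name_b) {
  a <- canonical_name(name_a)
  b <- canonical_name(name_b)
  if (!nzchar(a) && !nzchar(b)) {
    abort_validation("cannot compute lexical similarity of two empty names")
  }
  d <- as.integer(utils::adist(a, b)[1, 1])
  1 - d / max(nchar(a), nchar(b))
}

#' Pairwise pathway similarity matrix
#'
#' Scores every ordered pair of pathways from one database (against itself)
#' or two databases, with deterministic ordering by (resource, pathway_id).
#' The `content` metric is [overlap_coefficient()] on gene sets (with
#' `jaccard` and `dice` as alternatives); `lexical` is
#' [lexical_similarity()] on pathway names.
#'
#' @param db_rows A [pathway_database()] providing the rows.
#' @param db_cols Optional second database for the columns; defaults to
#'   `db_rows`, giving a square symmetric matrix with unit diagonal for
#'   non-empty gene sets.
#' @param metric One of `"content"`, `"lexical"`, `"jaccard"`, `"dice"`.
#' @return A numeric matrix with dimnames `"resource:pathway_id"` and a
#'   `metric` attribute.
#' @export
similarity_matrix <- function(db_rows, db_cols = NULL,
                              metric = c("content", "lexical", "jaccard", "dice")) {
  metric <- match.arg(metric)
  stopifnot(inherits(db_rows, "pathway_database"))
  if (is.null(db_cols)) db_cols <- db_rows
  stopifnot(inherits(db_cols, "pathway_database"))
  rows <- sorted_pathways(db_rows)
  cols <- sorted_pathways(db_cols)
  if (length(rows) == 0L || length(cols) == 0L) {
    abort_validation("similarity_matrix requires non-empty databases")
  }
  fun <- switch(metric,
    content = function(p, q) overlap_coefficient(p$genes, q$genes),
    jaccard = function(p, q) jaccard_index(p$genes, q$genes),
    dice = function(p, q) dice_coefficient(p$genes, q$genes),
    lexical = function(p, q) lexical_similarity(p$name, q$name)
  )
  m <- matrix(
    0, nrow = length(rows), ncol = length(cols),
    dimnames = list(pathway_key(rows), pathway_key(cols))
  )
  suppressWarnings(
    for (i in seq_along(rows)) {
      for (j in seq_along(cols)) {
        m[i, j] <- fun(rows[[i]], cols[[j]])
      }
    }
  )
  attr(m, "metric") <- metric
  m
}

sorted_pathways <- function(db) {
  ps <- db$pathways
  ps[order(vapply(ps, `[[`, character(1), "pathway_id"))]
}

#' Export a similarity matrix as TSV
#'
#' Writes the matrix with row and column headers of the form
#' `resource:pathway_id`.
#'
#' @param m Matrix from [similarity_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(m, path) {
  df <- data.frame(pathway = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
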