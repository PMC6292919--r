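# File formats: GMT gene-set files, plain gene lists, and the mapping TSV.
#
# GMT dialect: standard two fixed fields per line (name, description/id),
# then genes. Identifiers in the wild sit in either of the first two fields
# depending on the exporter, so the pathway_id is taken from field 2 when
# that column is non-empty and unique across the file, and from field 1
# otherwise. The rule is deterministic and applied per file.

RELATION_TYPES <- c("equivalentTo", "isPartOf")

MAPPING_TSV_COLUMNS <- c(
  "resource_1", "pathway_id_1", "name_1", "relation",
  "resource_2", "pathway_id_2", "name_2"
)

#' Read a GMT gene-set file into a pathway database
#'
#' Each non-blank line must have at least two tab-separated fields:
#' pathway name, description/identifier, then zero or more gene symbols.
#' Genes are normalized and deduplicated. Lines with fewer than two fields
#' raise a parse error naming the offending line.
#'
#' @param path Path to a GMT file.
#' @param resource Database name to stamp on every pathway.
#' @param version Version label for the returned database.
#' @return A [pathway_database()].
#' @export
read_gmt <- function(path, resource, version = "unversioned") {
  if (!file.exists(path)) {
    abort_io(sprintf("GMT file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 2L)
  if (length(bad) > 0L) {
    abort_parse(sprintf(
      "malformed GMT line %d in %s: fewer than 2 tab-separated fields",
      line_no[bad[1]], path
    ))
  }
  names_f <- vapply(fields, `[[`, character(1), 1L)
  desc_f <- vapply(fields, `[[`, character(1), 2L)
  # id from field 2 when usable for the whole file, else field 1
  use_desc <- length(desc_f) > 0L && all(nzchar(trimws(desc_f))) &&
    !anyDuplicated(desc_f)
  ids <- if (use_desc) desc_f else names_f
  if (anyDuplicated(ids)) {
    abort_validation(sprintf(
      "duplicate pathway identifier '%s' in %s",
      ids[duplicated(ids)][1], path
    ))
  }
  pathways <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    genes <- fields[[i]][-c(1L, 2L)]
    genes <- genes[nzchar(trimws(genes))]
    pathways[[i]] <- withCallingHandlers(
      pathway(resource, ids[i], names_f[i], genes),
      pathmapr_empty_geneset_warning = function(w) {
        warn_pathmapr(
          sprintf("%s line %d: %s", path, line_no[i], conditionMessage(w)),
          class = "pathmapr_empty_geneset_warning"
        )
        invokeRestart("muffleWarning")
      }
    )
  }
  pathway_database(resource, version, pathways)
}

#' Write a pathway database to a GMT file
#'
#' Genes are written in sorted order; field 1 carries the pathway name and
#' field 2 the pathway_id, so `read_gmt(write_gmt(db))` reproduces the same
#' (resource, pathway_id, name, genes) tuples.
#'
#' @param db A [pathway_database()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "pathway_database"))
  lines <- vapply(db$pathways, function(p) {
    paste(c(p$name, p$pathway_id, p$genes), collapse = "\t")
  }, character(1))
  ok <- tryCatch(
    {
      writeLines(unname(lines), path, useBytes = TRUE)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) abort_io(sprintf("cannot write GMT file: %s", path))
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are ignored; symbols are
#' normalized and deduplicated. An empty result triggers a warning.
#'
#' @param path Path to the gene list file.
#' @return Sorted character vector of normalized gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("gene list file not found: %s", path))
  }
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warn_pathmapr(sprintf("gene list %s contains no gene symbols", path))
    return(character())
  }
  sort(unique(normalize_gene_symbol(lines)))
}

#' Read a mapping-catalog TSV
#'
#' Expects a UTF-8 tab-separated file whose header names the seven columns
#' `resource_1, pathway_id_1, name_1, relation, resource_2, pathway_id_2,
#' name_2`. The relation must be `equivalentTo` (undirected equivalence) or
#' `isPartOf` (directed, side 1 the child, side 2 the parent); any other
#' value raises a parse error naming the line.
#'
#' @param path Path to a mapping TSV file.
#' @return A data.frame with the seven columns above.
#' @export
read_mapping_tsv <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("mapping TSV not found: %s", path))
  }
  df <- utils::read.delim(
    path,
    header = TRUE, sep = "\t", quote = "", comment.char = "",
    colClasses = "character", check.names = FALSE, fileEncoding = "UTF-8"
  )
  if (!identical(names(df), MAPPING_TSV_COLUMNS)) {
    abort_parse(sprintf(
      "mapping TSV %s must have header columns: %s",
      path, paste(MAPPING_TSV_COLUMNS, collapse = ", ")
    ))
  }
  bad <- which(!df$relation %in% RELATION_TYPES)
  if (length(bad) > 0L) {
    abort_parse(sprintf(
      "unknown relation '%s' at line %d of %s (expected equivalentTo or isPartOf)",
      df$relation[bad[1]], bad[1] + 1L, path
    ))
  }
  rownames(df) <- NULL
  df
}

#' Write mapping records to TSV
#'
#' @param records Data.frame with the seven mapping columns (see
#'   [read_mapping_tsv()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mapping_tsv <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(MAPPING_TSV_COLUMNS %in% names(records))) {
    abort_validation(sprintf(
      "mapping records must contain columns: %s",
      paste(MAPPING_TSV_COLUMNS, collapse = ", ")
    ))
  }
  records <- records[, MAPPING_TSV_COLUMNS, drop = FALSE]
  if (nrow(records) && any(!records$relation %in% RELATION_TYPES)) {
    abort_validation("mapping records contain an unknown relation type")
  }
  ok <- tryCatch(
    {
      utils::write.table(
        records, path,
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
        fileEncoding = "UTF-8"
      )
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) abort_io(sprintf("cannot write mapping TSV: %s", path))
  invisible(path)
}
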