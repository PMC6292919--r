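# Small in-code fixtures shared across test files.

quiet_pathway <- function(...) suppressWarnings(pathway(...))

# random gene set drawn from a synthetic alphabet of `pool` symbols
random_gene_set <- function(pool = 30L, min_size = 1L, max_size = 10L) {
  sample(sprintf("G%03d", seq_len(pool)), sample(min_size:max_size, 1L))
}

random_string <- function(max_len = 12L, alphabet = c("a", "b", "c", "d")) {
  n <- sample(0:max_len, 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# three-pathway toy database with known overlaps
toy_db <- function(resource = "TOY") {
  pathway_database(resource, "v1", list(
    pathway(resource, "P1", "alpha signaling", c("A", "B", "C")),
    pathway(resource, "P2", "beta signaling", c("B", "C", "D", "E")),
    pathway(resource, "P3", "gamma transport", c("F", "G"))
  ))
}

# database of random pathways over a shared pool
random_db <- function(resource, n = 6L, pool = 40L, min_size = 3L,
                      max_size = 12L, version = "v1") {
  ps <- lapply(seq_len(n), function(i) {
    pathway(resource, sprintf("P%02d", i),
            sprintf("%s pathway %d", tolower(resource), i),
            random_gene_set(pool, min_size, max_size))
  })
  pathway_database(resource, version, ps)
}
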