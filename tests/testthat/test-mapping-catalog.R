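mk <- function(resource, id, genes, name = id) pathway(resource, id, name, genes)

test_that("propose_mapping enforces shared genes, no self-mappings, and dedup", {
  p1 <- mk("KEGG", "K1", c("A", "B"), "Apoptosis")
  p2 <- mk("Reactome", "R1", c("B", "C"), "Apoptosis")
  p3 <- mk("Reactome", "R2", c("X", "Y"), "Other")

  cat <- mapping_catalog()
  cat <- propose_mapping(cat, p1, p2, "equivalentTo", "alice")
  expect_length(cat$mappings, 1L)
  m <- get_mapping(cat, p1, p2, "equivalentTo")
  expect_identical(m$state, "proposed")
  expect_identical(m$votes, c(alice = 1L))

  expect_error(propose_mapping(cat, p1, p3, "equivalentTo", "alice"),
               class = "pathmapr_validation_error")
  expect_error(propose_mapping(cat, p1, p1, "equivalentTo", "alice"),
               class = "pathmapr_validation_error")

  # duplicate proposal (either orientation) leaves the catalog unchanged
  cat2 <- propose_mapping(cat, p2, p1, "equivalentTo", "bob")
  expect_identical(cat2, cat)

  # isPartOf with shared genes is valid; intra-database mappings allowed
  child <- mk("KEGG", "K2", c("A", "B", "C"))
  cat3 <- propose_mapping(cat, child, p1, "isPartOf", "alice")
  expect_length(cat3$mappings, 2L)
})

test_that("equivalentTo is stored canonically and lookup is order-independent", {
  pa <- mk("ZDB", "Z1", c("A", "B"), "zeta")
  pb <- mk("ADB", "A1", c("A", "C"), "alpha")
  cat <- propose_mapping(mapping_catalog(), pa, pb, "equivalentTo", "alice")
  rec <- catalog_records(cat)
  expect_identical(rec$resource_1, "ADB")  # lexicographically smaller first
  expect_identical(rec$resource_2, "ZDB")
  expect_identical(get_mapping(cat, pa, pb, "equivalentTo"),
                   get_mapping(cat, pb, pa, "equivalentTo"))

  # isPartOf keeps child -> parent direction
  cat2 <- propose_mapping(mapping_catalog(), pa, pb, "isPartOf", "alice")
  rec2 <- catalog_records(cat2)
  expect_identical(rec2$resource_1, "ZDB")
  expect_identical(rec2$resource_2, "ADB")
})

test_that("voting: acceptance strictly above net 3, replacement semantics, rejection", {
  p1 <- mk("A", "P1", c("A", "B"))
  p2 <- mk("B", "P1", c("B", "C"))
  cat <- propose_mapping(mapping_catalog(), p1, p2, "equivalentTo", "alice")

  for (cur in c("bob", "carol", "dan")) {
    cat <- cast_vote(cat, p1, p2, "equivalentTo", cur, +1)
  }
  # net 4 > 3: accepted
  expect_identical(get_mapping(cat, p1, p2, "equivalentTo")$state, "accepted")

  # net exactly 3 is not enough
  cat3 <- propose_mapping(mapping_catalog(), p1, p2, "equivalentTo", "alice")
  cat3 <- cast_vote(cat3, p1, p2, "equivalentTo", "bob", +1)
  cat3 <- cast_vote(cat3, p1, p2, "equivalentTo", "carol", +1)
  expect_equal(sum(get_mapping(cat3, p1, p2, "equivalentTo")$votes), 3)
  expect_identical(get_mapping(cat3, p1, p2, "equivalentTo")$state, "proposed")

  # revoting replaces: net changes by 2
  cat4 <- cast_vote(cat, p1, p2, "equivalentTo", "dan", -1)
  expect_equal(sum(get_mapping(cat4, p1, p2, "equivalentTo")$votes), 2)
  expect_identical(get_mapping(cat4, p1, p2, "equivalentTo")$state, "proposed")

  # state is a pure function of the votes
  m <- get_mapping(cat4, p1, p2, "equivalentTo")
  expect_identical(m$state,
                   if (sum(m$votes) > 3) "accepted" else "proposed")

  expect_error(cast_vote(mapping_catalog(), p1, p2, "equivalentTo", "x", 1),
               class = "pathmapr_lookup_error")
  expect_error(cast_vote(cat, p1, p2, "equivalentTo", "x", 2),
               class = "pathmapr_validation_error")
})

test_that("suggest_mappings ranks identical pathways first and skips imported ones", {
  target <- mk("KEGG", "K1", c("A", "B", "C"), "alpha signaling")
  twin <- pathway("Reactome", "R1", "alpha signaling", c("A", "B", "C"))
  noise1 <- pathway("Reactome", "R2", "beta transport", c("A", "X", "Y", "Z"))
  noise2 <- pathway("Reactome", "R3", "something else", c("Q", "W"))
  db <- pathway_database("Reactome", "v", list(twin, noise1, noise2))

  s <- suggest_mappings(target, db)
  expect_identical(s$pathway_id[1], "R1")
  expect_equal(s$content_similarity[1], 1)
  expect_equal(s$lexical_similarity[1], 1)
  expect_equal(s$rank, seq_len(nrow(s)))
  expect_equal(s$content_similarity[s$pathway_id == "R3"], 0)

  # imported pathways are suppressed from suggestions
  imp <- pathway("Reactome", "R1", "alpha signaling", c("A", "B", "C"),
                 imported = TRUE)
  db2 <- pathway_database("Reactome", "v", list(imp, noise1, noise2))
  s2 <- suggest_mappings(target, db2)
  expect_false("R1" %in% s2$pathway_id)

  # content-only and lexical-only combiners rank on a single metric
  s3 <- suggest_mappings(target, db, combiner = "lexical")
  expect_equal(s3$score, s3$lexical_similarity)
})

test_that("consensus merge accepts majority mappings and flags minority/conflicts", {
  p1 <- mk("A", "P1", c("A", "B"))
  p2 <- mk("B", "P1", c("B", "C"))
  q1 <- mk("A", "P2", c("D", "E"))
  q2 <- mk("B", "P2", c("E", "F"))
  r1 <- mk("A", "P3", c("G", "H"))
  r2 <- mk("B", "P3", c("H", "I"))

  # shared mapping in all three; q only in catalog 1; r with conflicting types
  c1 <- propose_mapping(mapping_catalog(), p1, p2, "equivalentTo", "alice")
  c1 <- propose_mapping(c1, q1, q2, "equivalentTo", "alice")
  c1 <- propose_mapping(c1, r1, r2, "equivalentTo", "alice")
  c2 <- propose_mapping(mapping_catalog(), p1, p2, "equivalentTo", "bob")
  c2 <- propose_mapping(c2, r1, r2, "isPartOf", "bob")
  c3 <- propose_mapping(mapping_catalog(), p1, p2, "equivalentTo", "carol")

  out <- merge_consensus(list(c1, c2, c3))
  m <- get_mapping(out$catalog, p1, p2, "equivalentTo")
  expect_identical(m$state, "accepted")
  mq <- get_mapping(out$catalog, q1, q2, "equivalentTo")
  expect_identical(mq$state, "proposed")
  expect_true("minority" %in% out$conflicts$type)
  expect_true("relation_conflict" %in% out$conflicts$type)
  # conflicting pair is never auto-resolved
  expect_null(get_mapping(out$catalog, r1, r2, "equivalentTo"))
  expect_null(get_mapping(out$catalog, r1, r2, "isPartOf"))

  # order independence
  out2 <- merge_consensus(list(c3, c1, c2))
  expect_identical(catalog_records(out2$catalog)[, 1:7],
                   catalog_records(out$catalog)[, 1:7])
  expect_identical(out2$conflicts, out$conflicts)
})

test_that("hierarchy inference: transitivity, symmetry, substitution, idempotence", {
  recs <- data.frame(
    resource_1 = c("X", "X", "X"),
    pathway_id_1 = c("A", "B", "E"),
    relation = c("isPartOf", "isPartOf", "equivalentTo"),
    resource_2 = c("X", "X", "X"),
    pathway_id_2 = c("B", "C", "A"),
    stringsAsFactors = FALSE
  )
  closed <- infer_hierarchy_records(recs)
  key <- function(df) paste(df$relation, df$pathway_id_1, df$pathway_id_2)
  k <- key(closed)
  expect_true("isPartOf A C" %in% k)       # transitivity
  expect_true("equivalentTo A E" %in% k)   # symmetry
  expect_true("isPartOf E B" %in% k)       # substitution through equivalence
  expect_true("isPartOf E C" %in% k)
  inferred <- closed$inferred[match("isPartOf A C", k)]
  expect_true(inferred)
  expect_false(closed$inferred[match("isPartOf A B", k)])

  # idempotence: closing the closure adds nothing
  again <- infer_hierarchy_records(closed[, names(recs)])
  expect_identical(again[, names(recs)], closed[, names(recs)])
  expect_false(any(infer_hierarchy_records(closed[, names(recs)])$inferred &
                     !closed$inferred))
})

test_that("a cycle in the isPartOf closure raises a consistency error naming it", {
  recs <- data.frame(
    resource_1 = c("X", "X"), pathway_id_1 = c("A", "B"),
    relation = c("isPartOf", "isPartOf"),
    resource_2 = c("X", "X"), pathway_id_2 = c("B", "A"),
    stringsAsFactors = FALSE
  )
  err <- expect_error(infer_hierarchy_records(recs),
                      class = "pathmapr_consistency_error")
  expect_match(conditionMessage(err), "X:A")
  expect_match(conditionMessage(err), "X:B")
})

test_that("infer_hierarchy uses only accepted catalog mappings", {
  a <- mk("X", "A", c("G1", "G2"))
  b <- mk("X", "B", c("G2", "G3"))
  cat <- propose_mapping(mapping_catalog(), a, b, "isPartOf", "alice")
  expect_equal(nrow(infer_hierarchy(cat)), 0L)
  for (cur in c("bob", "carol", "dan", "eve")) {
    cat <- cast_vote(cat, a, b, "isPartOf", cur, +1)
  }
  inf <- infer_hierarchy(cat)
  expect_equal(nrow(inf), 1L)
  expect_identical(inf$relation, "isPartOf")
})

test_that("catalog summary counts pairs and unmapped fractions", {
  dbA <- pathway_database("A", "v", list(
    mk("A", "P1", c("A", "B")), mk("A", "P2", c("C", "D"))
  ))
  dbB <- pathway_database("B", "v", list(
    mk("B", "P1", c("B", "E")), mk("B", "P2", c("F", "G"))
  ))
  # empty catalog: everything unmapped
  s0 <- catalog_summary(mapping_catalog(), list(dbA, dbB))
  expect_equal(s0$unmapped$unmapped_fraction, c(1, 1))
  expect_equal(nrow(s0$pair_counts), 0L)

  cat <- propose_mapping(mapping_catalog(), dbA$pathways[["P1"]],
                         dbB$pathways[["P1"]], "equivalentTo", "alice")
  for (cur in c("bob", "carol", "dan", "eve")) {
    cat <- cast_vote(cat, dbA$pathways[["P1"]], dbB$pathways[["P1"]],
                     "equivalentTo", cur, +1)
  }
  s1 <- catalog_summary(cat, list(dbA, dbB))
  expect_equal(s1$pair_counts$n, 1L)
  expect_identical(s1$pair_counts$relation, "equivalentTo")
  expect_equal(s1$unmapped$unmapped_fraction, c(0.5, 0.5))
})

test_that("catalogs round-trip through records, TSV and JSON exports", {
  p1 <- mk("A", "P1", c("A", "B"), "one")
  p2 <- mk("B", "P1", c("B", "C"), "uno")
  cat <- propose_mapping(mapping_catalog(), p1, p2, "equivalentTo", "alice")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(cat, f, accepted_only = FALSE)
  back <- read_mapping_tsv(f)
  expect_equal(nrow(back), 1L)
  expect_identical(back$relation, "equivalentTo")

  dbs <- list(pathway_database("A", "v", list(p1)),
              pathway_database("B", "v", list(p2)))
  cat2 <- catalog_from_records(back, dbs, proposer = "import")
  expect_identical(catalog_records(cat2)[, 1:7], catalog_records(cat)[, 1:7])

  fj <- withr::local_tempfile(fileext = ".json")
  write_catalog_json(cat, fj)
  j <- jsonlite::read_json(fj)
  expect_equal(length(j$mappings), 1L)
  expect_identical(j$mappings[[1]]$state, "proposed")
})
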